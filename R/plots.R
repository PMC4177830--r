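#' @export
autoplot.compartment_set <- function(object, ...) {
  params <- attr(object, "params")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$diameter_um)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = params$min_diameter_um,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "Equivalent diameter (µm)", y = "Compartments")
}

#' @export
autoplot.airspace_mask <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$mask)),
                           col = seq_len(ncol(object$mask)))
  df$airspace <- as.vector(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$airspace)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey20",
                                          `TRUE` = "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Airspace")
}

#' Plot per-image D-index values by group
#'
#' @param data Tibble with per-image values, e.g. `run_pipeline()$d2`.
#' @param value,group Columns, unquoted.
#' @return A ggplot.
#' @export
plot_d_index_groups <- function(data, value = d2_um, group = group) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ group }}, y = {{ value }})) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::labs(y = "D2 (µm)", x = NULL)
}
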