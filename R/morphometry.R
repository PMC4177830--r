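#' Morphometry parameters
#'
#' @param connectivity Pixel connectivity for compartment labeling, 4
#'   (default; conservative against single-pixel bridges merging distinct
#'   alveoli) or 8.
#' @param exclude_border Drop compartments touching the image border from
#'   downstream diameter vectors (default `TRUE`; truncated compartments
#'   bias the index unpredictably).
#' @param min_diameter_um Minimum equivalent diameter retained, in
#'   micrometers. Compartments smaller than this are disregarded; the
#'   default of 138 um targets enlarged airspaces rather than normal
#'   alveoli.
#' @return A list of class `morphometry_params`.
#' @export
morphometry_params <- function(connectivity = 4, exclude_border = TRUE,
                               min_diameter_um = 138) {
  if (!connectivity %in% c(4, 8)) {
    abort("`connectivity` must be 4 or 8.",
          class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(min_diameter_um, "min_diameter_um", min = 0)
  structure(list(connectivity = as.integer(connectivity),
                 exclude_border = isTRUE(exclude_border),
                 min_diameter_um = min_diameter_um),
            class = "morphometry_params")
}

#' Label connected airspace compartments
#'
#' Splits the airspace class of a binary mask into connected components and
#' converts their sizes from pixels to micrometers. Each compartment gets a
#' physical area `area_um2 = n_px * px_size_um^2` and an equivalent diameter
#' `diameter_um = 2 * sqrt(area_um2 / pi)` (the diameter of the circle of
#' equal area). Compartments touching the image border are flagged.
#'
#' @param mask An [airspace_mask()] or logical matrix.
#' @param params A [morphometry_params()] list.
#' @param px_size_um Required when `mask` is a bare matrix.
#' @return A tibble of class `compartment_set` with one row per compartment:
#'   `compartment`, `n_px`, `area_um2`, `diameter_um`, `touches_border`.
#'   Attributes: `labels` (the label matrix), `px_size_um`, `params`. An
#'   empty mask yields an empty set.
#' @export
label_compartments <- function(mask, params = morphometry_params(),
                               px_size_um = NULL) {
  if (inherits(mask, "airspace_mask")) {
    px_size_um <- mask$px_size_um
    m <- mask$mask
  } else {
    if (is.null(px_size_um)) {
      abort("`px_size_um` is required for a bare matrix mask.",
            class = "airspace_error_validation")
    }
    m <- mask
    storage.mode(m) <- "logical"
  }
  stop_if_not_scalar_number(px_size_um, "px_size_um", min = 0,
                            strict_min = TRUE)
  labels <- .label_components(m, params$connectivity)
  k <- max(labels)
  if (k == 0) {
    cs <- tibble::tibble(compartment = integer(), n_px = integer(),
                         area_um2 = numeric(), diameter_um = numeric(),
                         touches_border = logical())
  } else {
    n_px <- tabulate(labels[labels > 0], nbins = k)
    border <- sort(unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)])))
    border <- border[border > 0]
    area <- n_px * px_size_um^2
    cs <- tibble::tibble(
      compartment = seq_len(k),
      n_px = n_px,
      area_um2 = area,
      diameter_um = 2 * sqrt(area / pi),
      touches_border = seq_len(k) %in% border
    )
  }
  structure(cs, labels = labels, px_size_um = px_size_um, params = params,
            class = c("compartment_set", class(cs)))
}

#' Filter compartment diameters by a minimum size
#'
#' Keeps equivalent diameters at or above `min_diameter_um`; compartments
#' smaller than the threshold are disregarded. Border-touching compartments
#' are dropped first when the set was labeled with `exclude_border = TRUE`.
#'
#' @param cs A [label_compartments()] result.
#' @param min_diameter_um Threshold in micrometers (>= 0); defaults to the
#'   value in the set's [morphometry_params()].
#' @return Numeric vector of retained diameters (um) with attributes
#'   `n_kept`, `n_removed` (below threshold) and `n_border_excluded`.
#' @export
filter_compartments <- function(cs, min_diameter_um = NULL) {
  stopifnot(inherits(cs, "compartment_set"))
  params <- attr(cs, "params")
  thr <- min_diameter_um %||% params$min_diameter_um
  if (!is.numeric(thr) || length(thr) != 1 || !is.finite(thr) || thr < 0) {
    abort("`min_diameter_um` must be a single non-negative number.",
          class = "airspace_error_validation")
  }
  d_all <- cs$diameter_um
  border <- cs$touches_border
  if (isTRUE(params$exclude_border)) {
    n_border <- sum(border)
    d_all <- d_all[!border]
  } else {
    n_border <- 0L
  }
  keep <- d_all >= thr
  structure(d_all[keep],
            n_kept = sum(keep), n_removed = sum(!keep),
            n_border_excluded = n_border, min_diameter_um = thr)
}

#' Moment-ratio airspace diameter index
#'
#' Summarises a distribution of airspace equivalent diameters by the
#' moment-ratio
#' \deqn{D_k = \frac{\sum_i d_i^{k+1}}{\sum_i d_i^k}}
#' so that larger airspaces are weighed more heavily as `k` grows: `D_0` is
#' the arithmetic mean and `D_{k+1} >= D_k`. The default `k = 2` (the D2
#' index) is sensitive to the few enlarged airspaces that mark early or
#' mild emphysema while remaining bounded by `max(d)`.
#'
#' @param d Non-empty vector of positive diameters in micrometers, typically
#'   from [filter_compartments()].
#' @param k Moment order, integer >= 0.
#' @return An object of class `dindex_result`: list with `k`, `value_um`,
#'   `n_compartments_used`, `n_filtered_out`, `threshold_um` (the latter two
#'   taken from [filter_compartments()] attributes when present, else 0).
#' @export
d_index <- function(d, k = 2) {
  stop_if_not_scalar_number(k, "k", min = 0)
  if (length(d) == 0) {
    abort("No compartments left to summarise.",
          class = "airspace_error_empty_compartments")
  }
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    abort("Diameters must all be positive and finite.",
          class = "airspace_error_validation")
  }
  value <- sum(d^(k + 1)) / sum(d^k)
  structure(list(k = k, value_um = value,
                 n_compartments_used = length(d),
                 n_filtered_out = attr(d, "n_removed") %||% 0L,
                 threshold_um = attr(d, "min_diameter_um") %||% 0),
            class = "dindex_result")
}

#' @export
print.dindex_result <- function(x, ...) {
  cat(sprintf("D_%d = %.2f um (%d compartments used, %d below %.0f um filtered out)\n",
              x$k, x$value_um, x$n_compartments_used, x$n_filtered_out,
              x$threshold_um))
  invisible(x)
}

#' @export
tidy.dindex_result <- function(x, ...) {
  tibble::tibble(k = x$k, value_um = x$value_um,
                 n_compartments_used = x$n_compartments_used,
                 n_filtered_out = x$n_filtered_out,
                 threshold_um = x$threshold_um)
}

#' D-index of a segmented mask, end to end
#'
#' Convenience composition: [label_compartments()], [filter_compartments()],
#' [d_index()].
#'
#' @inheritParams label_compartments
#' @param k Moment order.
#' @return A `dindex_result`.
#' @export
d_index_from_mask <- function(mask, params = morphometry_params(), k = 2,
                              px_size_um = NULL) {
  cs <- label_compartments(mask, params, px_size_um = px_size_um)
  d_index(filter_compartments(cs), k = k)
}
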