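#' Default pipeline configuration
#'
#' A nested list covering every stage's parameters, the output directory and
#' the master seed. The same structure can be read from a YAML file with
#' [read_pipeline_config()]. Unknown keys anywhere in a supplied config are
#' rejected by [run_pipeline()] before any computation.
#'
#' @param output_dir Where run outputs are written.
#' @param seed Master seed; per-image seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(output_dir = tempfile("airspace_run_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    simulate = list(
      n_images_per_group = 3L,
      severities = list(low = 0.2, high = 0.8),
      image = list(width_px = 256L, height_px = 256L, px_size_um = 16,
                   diameter_log_mean = log(60), diameter_log_sd = 0.5,
                   target_area_fraction = 0.5, tissue_mean = 0.45,
                   airspace_mean = 0.85, noise_sd = 0.05,
                   bias_amplitude = 0.1)
    ),
    segment = list(
      fcm = list(m = 2, max_iter = 100, tol = 1e-4),
      graph_cut = list(lambda = 0.5, epsilon = 1e-6)
    ),
    quantify = list(connectivity = 4L, exclude_border = TRUE,
                    min_diameter_um = 138, k = 2L),
    compare = list(alpha = 0.05)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [default_pipeline_config()] structure;
#'   missing keys fall back to defaults, unknown keys are rejected.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user, "config")
}

merge_config <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s) under %s: %s", where,
                  paste(unknown, collapse = ", ")),
          class = "airspace_error_config")
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]])) {
        abort(sprintf("Key '%s' under %s must be a section.", k, where),
              class = "airspace_error_config")
      }
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(where, "$", k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(config) {
  merge_config(default_pipeline_config(), config, "config")
}

#' Run the simulate-segment-quantify-compare pipeline
#'
#' Executes the requested stages in order on synthetic image groups:
#' generates one image set per severity group, segments each image
#' ([segment_airspaces()]), quantifies the filtered D-index
#' ([d_index_from_mask()]), and compares groups
#' ([compare_genotype_groups()]). Per-image compartment tables and the
#' per-image D-index table are written as CSV, the group comparison and run
#' metadata as JSON, and the fully resolved configuration as YAML next to
#' the outputs. Identical configuration and seed give identical outputs.
#'
#' @param config Nested list as [default_pipeline_config()]; partial configs
#'   are completed with defaults, unknown keys raise a validation error
#'   before any computation.
#' @return Invisibly, a list with `d2` (per-image tibble), `comparison`
#'   (test report tibble) and `paths` of written files.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  mp <- morphometry_params(connectivity = config$quantify$connectivity,
                           exclude_border = config$quantify$exclude_border,
                           min_diameter_um = config$quantify$min_diameter_um)
  fp <- do.call(fcm_params, config$segment$fcm)
  gp <- do.call(graph_cut_params, config$segment$graph_cut)

  rows <- list()
  comp_paths <- character(0)
  img_counter <- 0L
  for (gname in names(config$simulate$severities)) {
    sev <- config$simulate$severities[[gname]]
    for (i in seq_len(config$simulate$n_images_per_group)) {
      img_counter <- img_counter + 1L
      sp <- do.call(histology_sim_params, c(
        config$simulate$image,
        list(severity = sev, seed = config$seed * 10000L + img_counter)))
      sim <- generate_alveolar_image(sp)
      mask <- segment_airspaces(sim$image, fp, gp)
      cs <- label_compartments(mask, mp)
      d2 <- d_index(filter_compartments(cs), k = config$quantify$k)
      cs_path <- file.path(config$output_dir,
                           sprintf("compartments_%s_%02d.csv", gname, i))
      write.csv(as.data.frame(cs), cs_path, row.names = FALSE)
      comp_paths <- c(comp_paths, cs_path)
      rows[[img_counter]] <- tibble::tibble(
        image_id = sprintf("%s_%02d", gname, i), group = gname,
        severity = sev, d2_um = d2$value_um,
        n_compartments_used = d2$n_compartments_used,
        n_filtered_out = d2$n_filtered_out,
        airspace_fraction = attr(mask, "airspace_fraction"),
        energy = attr(mask, "energy"), fcm_iterations = attr(mask, "n_iter"))
    }
  }
  d2_tbl <- dplyr::bind_rows(rows)
  comparison <- compare_genotype_groups(d2_tbl, value = d2_um, group = group,
                                        alpha = config$compare$alpha)

  d2_path <- file.path(config$output_dir, "d2_per_image.csv")
  write.csv(as.data.frame(d2_tbl), d2_path, row.names = FALSE)
  report_path <- file.path(config$output_dir, "group_report.json")
  jsonlite::write_json(
    list(seed = config$seed,
         parameters = config,
         d_index = d2_tbl,
         comparison = comparison),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_path <- file.path(config$output_dir, "resolved_config.yaml")
  yaml::write_yaml(config, cfg_path)

  invisible(list(d2 = d2_tbl, comparison = comparison,
                 paths = list(d2 = d2_path, report = report_path,
                              config = cfg_path, compartments = comp_paths)))
}
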