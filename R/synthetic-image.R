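#' Parameters for the synthetic alveolar histology generator
#'
#' The generator emulates the features of an H&E lung section that matter to
#' the segmentation and morphometry stages: bright airspaces on darker
#' tissue, additive acquisition noise, a smooth multiplicative illumination
#' ramp, and an airspace-size distribution under analytic control. Airspaces
#' are a Boolean model — Poisson-sampled disc centers with lognormal
#' equivalent diameters, rasterised as a union — which ties the planted
#' diameter distribution directly to the quantity the D-index summarises.
#'
#' `severity` shifts the whole diameter distribution upward by a factor
#' `3^severity` (so severity 1 triples the median diameter, emulating
#' progressive airspace enlargement) while the disc density is scaled down
#' to hold the expected airspace area fraction at `target_area_fraction`.
#'
#' @param width_px,height_px Image size in pixels.
#' @param px_size_um Micrometers per pixel. A stated magnification does not
#'   determine this, so it is always explicit; 2 um/px is a plausible value
#'   for a 10x objective.
#' @param severity Airspace-enlargement severity in \[0, 1\].
#' @param diameter_log_mean,diameter_log_sd Lognormal parameters of the
#'   airspace equivalent diameter in micrometers at severity 0 (defaults:
#'   median 60 um, sdlog 0.5 — the scale of normal-to-mildly-enlarged mouse
#'   alveolar airspaces).
#' @param target_area_fraction Expected airspace area fraction in (0, 1).
#' @param tissue_mean,airspace_mean Class intensities in (0, 1); airspace
#'   must be brighter and separated from tissue by at least four noise
#'   standard deviations so the two classes are distinguishable.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bias_amplitude Peak deviation of the multiplicative planar
#'   illumination ramp from 1 (>= 0).
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A list of class `histology_sim_params`.
#' @export
histology_sim_params <- function(width_px = 1024, height_px = 1024,
                                 px_size_um = 2, severity = 0.3,
                                 diameter_log_mean = log(60),
                                 diameter_log_sd = 0.5,
                                 target_area_fraction = 0.5,
                                 tissue_mean = 0.45, airspace_mean = 0.85,
                                 noise_sd = 0.05, bias_amplitude = 0.1,
                                 seed = 1L) {
  stop_if_not_scalar_number(width_px, "width_px", min = 2)
  stop_if_not_scalar_number(height_px, "height_px", min = 2)
  stop_if_not_scalar_number(px_size_um, "px_size_um", min = 0,
                            strict_min = TRUE)
  stop_if_not_probability(severity, "severity")
  stop_if_not_scalar_number(diameter_log_mean, "diameter_log_mean")
  stop_if_not_scalar_number(diameter_log_sd, "diameter_log_sd", min = 0)
  stop_if_not_scalar_number(target_area_fraction, "target_area_fraction",
                            min = 0, max = 1, strict_min = TRUE)
  if (target_area_fraction >= 1) {
    abort("`target_area_fraction` must be below 1.",
          class = "airspace_error_validation")
  }
  stop_if_not_probability(tissue_mean, "tissue_mean")
  stop_if_not_probability(airspace_mean, "airspace_mean")
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stop_if_not_scalar_number(bias_amplitude, "bias_amplitude", min = 0)
  if (airspace_mean - tissue_mean < 4 * noise_sd) {
    abort("airspace_mean - tissue_mean must be at least 4 * noise_sd.",
          class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(seed, "seed")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 px_size_um = px_size_um, severity = severity,
                 diameter_log_mean = diameter_log_mean,
                 diameter_log_sd = diameter_log_sd,
                 target_area_fraction = target_area_fraction,
                 tissue_mean = tissue_mean, airspace_mean = airspace_mean,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "histology_sim_params")
}

#' Generate a synthetic alveolar histology image with ground truth
#'
#' Draws a Boolean disc model (see [histology_sim_params()]): the number of
#' discs is Poisson with intensity chosen so the expected union covers
#' `target_area_fraction` of the image
#' (`E[covered fraction] = 1 - exp(-total expected disc area / image area)`),
#' centers are uniform, and diameters lognormal scaled by `3^severity`.
#' The intensity image is `tissue_mean` plus the class contrast on the disc
#' union plus Gaussian noise, multiplied by a planar illumination ramp whose
#' extreme corners are exactly `1 - bias_amplitude` and `1 + bias_amplitude`,
#' then clamped to \[0, 1\].
#'
#' The ground truth is the exact rasterised disc union; its compartment
#' diameters are computed from that mask with the same geometry as the
#' morphometry stage (`d = 2 sqrt(A / pi)`).
#'
#' @param params A [histology_sim_params()] list.
#' @return A list of class `alveolar_sim`: `image` (a [calibrated_image()]),
#'   `ground_truth` (list with `mask` logical matrix, `compartments` — a
#'   [label_compartments()] tibble — and `compartment_diameters_um`), and
#'   `params`.
#' @export
generate_alveolar_image <- function(params = histology_sim_params()) {
  stopifnot(inherits(params, "histology_sim_params"))
  withr::with_seed(params$seed, {
    h <- params$height_px; w <- params$width_px
    meanlog <- params$diameter_log_mean + params$severity * log(3)
    sdlog <- params$diameter_log_sd
    # expected disc area in px^2 for lognormal diameters in um
    e_d2_um2 <- exp(2 * meanlog + 2 * sdlog^2)
    e_area_px <- (pi / 4) * e_d2_um2 / params$px_size_um^2
    total_area_needed <- -log(1 - params$target_area_fraction) * h * w
    n_discs <- rpois(1, total_area_needed / e_area_px)
    if (n_discs == 0) {
      abort("Degenerate geometry: zero airspaces sampled; enlarge the image or the area fraction.",
            class = "airspace_error_degenerate_geometry")
    }
    cx <- runif(n_discs, 0.5, w + 0.5)
    cy <- runif(n_discs, 0.5, h + 0.5)
    r_px <- rlnorm(n_discs, meanlog, sdlog) / 2 / params$px_size_um

    mask <- matrix(FALSE, h, w)
    for (i in seq_len(n_discs)) {
      r0 <- max(1L, floor(cy[i] - r_px[i])); r1 <- min(h, ceiling(cy[i] + r_px[i]))
      c0 <- max(1L, floor(cx[i] - r_px[i])); c1 <- min(w, ceiling(cx[i] + r_px[i]))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      inside <- outer((rr - cy[i])^2, (cc - cx[i])^2, `+`) <= r_px[i]^2
      mask[rr, cc] <- mask[rr, cc] | inside
    }

    base <- params$tissue_mean +
      (params$airspace_mean - params$tissue_mean) * mask +
      matrix(rnorm(h * w, 0, params$noise_sd), h, w)
    # planar ramp along the main diagonal, corners exactly 1 +- amplitude
    tt <- (outer((seq_len(h) - 1) / (h - 1), (seq_len(w) - 1) / (w - 1), `+`) - 1)
    bias <- 1 + params$bias_amplitude * tt
    img <- pmin(pmax(base * bias, 0), 1)

    cs <- label_compartments(mask, morphometry_params(),
                             px_size_um = params$px_size_um)
    structure(list(
      image = calibrated_image(img, params$px_size_um),
      ground_truth = list(mask = mask, compartments = cs,
                          compartment_diameters_um = cs$diameter_um),
      params = params),
      class = "alveolar_sim")
  })
}
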