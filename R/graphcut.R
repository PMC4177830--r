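#' Parameters for graph-cut refinement
#'
#' @param lambda Non-negative weight of the pairwise (smoothness) term.
#' @param sigma_i Intensity contrast scale of the edge weights; `NULL` means
#'   the mean absolute intensity difference between 4-neighbours (1 if that
#'   is 0).
#' @param epsilon Floor applied to memberships before taking logs, in (0, 1).
#' @param airspace_class `"bright"` (default, H&E airspaces are bright) or
#'   `"dark"` for dark-field inputs.
#' @return A list of class `graph_cut_params`.
#' @export
graph_cut_params <- function(lambda = 0.5, sigma_i = NULL, epsilon = 1e-6,
                             airspace_class = c("bright", "dark")) {
  stop_if_not_scalar_number(lambda, "lambda", min = 0)
  if (!is.null(sigma_i)) {
    stop_if_not_scalar_number(sigma_i, "sigma_i", min = 0, strict_min = TRUE)
  }
  stop_if_not_scalar_number(epsilon, "epsilon", min = 0, max = 1,
                            strict_min = TRUE)
  if (epsilon >= 1) {
    abort("`epsilon` must be below 1.", class = "airspace_error_validation")
  }
  structure(list(lambda = lambda, sigma_i = sigma_i, epsilon = epsilon,
                 airspace_class = match.arg(airspace_class)),
            class = "graph_cut_params")
}

#' Binary airspace mask
#'
#' @param mask Logical matrix, `TRUE` = airspace.
#' @param px_size_um Micrometers per pixel.
#' @return An object of class `airspace_mask`.
#' @export
airspace_mask <- function(mask, px_size_um) {
  if (!is.matrix(mask)) {
    abort("`mask` must be a matrix.", class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(px_size_um, "px_size_um", min = 0,
                            strict_min = TRUE)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, px_size_um = px_size_um),
            class = "airspace_mask")
}

#' @export
print.airspace_mask <- function(x, ...) {
  cat(sprintf("<airspace_mask> %d x %d px, %.3g um/px, airspace fraction %.3f\n",
              nrow(x$mask), ncol(x$mask), x$px_size_um, mean(x$mask)))
  invisible(x)
}

# Unary costs (-log membership with floor) for labels 0 (tissue) and
# 1 (airspace); airspace is the class with the larger centroid unless
# airspace_class = "dark".
gc_unaries <- function(field, params) {
  air <- if (params$airspace_class == "bright") which.max(field$v) else
    which.min(field$v)
  tis <- 3L - air
  list(theta0 = -log(pmax(field$u[, , tis], params$epsilon)),
       theta1 = -log(pmax(field$u[, , air], params$epsilon)))
}

gc_pairwise <- function(image, params) {
  e <- grid_edges_4(nrow(image$pixels), ncol(image$pixels))
  dx <- image$pixels[e[, "u"] + 1L] - image$pixels[e[, "v"] + 1L]
  sigma <- params$sigma_i %||% {
    s <- mean(abs(dx))
    if (s == 0) 1 else s
  }
  list(edges = e, w = params$lambda * exp(-dx^2 / (2 * sigma^2)))
}

#' Potts segmentation energy of a labeling
#'
#' The energy minimised by [graph_cut_refine()]:
#' \deqn{E(L) = \sum_p -\log \max(u_{p,L(p)}, \epsilon) +
#'   \lambda \sum_{(p,q) \in N_4} [L(p) \ne L(q)]
#'   e^{-(x_p - x_q)^2 / (2\sigma_i^2)}}
#' Exposed so any candidate labeling can be scored against the one the cut
#' returns.
#'
#' @param labels Logical matrix (or [airspace_mask()]), `TRUE` = airspace.
#' @param field A [fcm_bias()] result.
#' @param image The [calibrated_image()] the field was fit to.
#' @param params A [graph_cut_params()] list.
#' @return The scalar energy.
#' @export
graph_cut_energy <- function(labels, field, image,
                             params = graph_cut_params()) {
  if (inherits(labels, "airspace_mask")) labels <- labels$mask
  th <- gc_unaries(field, params)
  pw <- gc_pairwise(image, params)
  lab <- as.logical(labels)
  unary <- sum(ifelse(lab, th$theta1, th$theta0))
  cut <- lab[pw$edges[, "u"] + 1L] != lab[pw$edges[, "v"] + 1L]
  unary + sum(pw$w[cut])
}

#' Refine a fuzzy pre-segmentation by exact graph cut
#'
#' Computes the global minimiser of the two-label Potts energy described in
#' [graph_cut_energy()] — unary costs from the fuzzy class memberships,
#' contrast-modulated pairwise costs on a 4-neighbourhood — by
#' Boykov-Kolmogorov max-flow/min-cut on the standard s-t graph
#' construction. Because the pairwise term is submodular the returned
#' labeling attains the exact global minimum, so refinement can never have
#' higher energy than the max-membership labeling.
#'
#' @param field A [fcm_bias()] result.
#' @param image The [calibrated_image()] the field was fit to; shapes must
#'   match.
#' @param params A [graph_cut_params()] list.
#' @return An [airspace_mask()] with attributes `energy` (energy of the
#'   returned labeling) and `energy_argmax` (energy of the max-membership
#'   labeling, for comparison).
#' @export
graph_cut_refine <- function(field, image, params = graph_cut_params()) {
  stopifnot(inherits(field, "membership_field"),
            inherits(image, "calibrated_image"))
  h <- dim(field$u)[1]; w <- dim(field$u)[2]
  if (h != nrow(image$pixels) || w != ncol(image$pixels)) {
    abort("Membership field and image shapes differ.",
          class = "airspace_error_validation")
  }
  th <- gc_unaries(field, params)
  pw <- gc_pairwise(image, params)
  lab <- .bk_min_cut(h * w, as.vector(th$theta0), as.vector(th$theta1),
                     pw$edges[, "u"], pw$edges[, "v"], pw$w)
  mask <- airspace_mask(matrix(lab, h, w), image$px_size_um)
  attr(mask, "energy") <- graph_cut_energy(mask$mask, field, image, params)
  argmax <- th$theta1 < th$theta0
  attr(mask, "energy_argmax") <- graph_cut_energy(argmax, field, image, params)
  mask
}

#' Segment alveolar airspaces in a calibrated histology image
#'
#' The full two-stage segmentation: [fcm_bias()] pre-segmentation into two
#' classes with luminance-inhomogeneity correction, then [graph_cut_refine()]
#' with energies given by the class membership functions.
#'
#' @param image A [calibrated_image()].
#' @param fcm An [fcm_params()] list.
#' @param gc A [graph_cut_params()] list.
#' @return An [airspace_mask()] with attributes `n_iter`, `energy`,
#'   `energy_argmax` and `airspace_fraction`.
#' @export
segment_airspaces <- function(image, fcm = fcm_params(),
                              gc = graph_cut_params()) {
  field <- fcm_bias(image, fcm)
  mask <- graph_cut_refine(field, image, gc)
  attr(mask, "n_iter") <- field$n_iter
  attr(mask, "airspace_fraction") <- mean(mask$mask)
  mask
}
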