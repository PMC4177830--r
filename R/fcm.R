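#' Parameters for bias-corrected fuzzy c-means pre-segmentation
#'
#' The pre-segmentation clusters pixel intensities into two fuzzy classes
#' (tissue and airspace) while jointly estimating a smooth multiplicative
#' illumination (bias) field, so that a luminance gradient across the slide
#' does not pull one side of the image into the wrong class.
#'
#' @param m Fuzzifier, > 1. `m = 2` is the common default; larger values give
#'   softer memberships.
#' @param max_iter Maximum number of alternating updates.
#' @param tol Convergence tolerance on the maximum per-pixel membership
#'   change between iterations.
#' @param bias_smooth_sigma Gaussian smoothing scale of the bias field in
#'   pixels; `NULL` means `min(nrow, ncol) / 4`, i.e. the field varies only
#'   on the scale of the whole image.
#' @param bias_clamp Length-2 numeric, lower and upper clamp applied to the
#'   bias field after each re-estimate.
#' @return A list of class `fcm_params`.
#' @export
fcm_params <- function(m = 2, max_iter = 100, tol = 1e-4,
                       bias_smooth_sigma = NULL, bias_clamp = c(0.5, 2)) {
  stop_if_not_scalar_number(m, "m", min = 1, strict_min = TRUE)
  stop_if_not_scalar_number(max_iter, "max_iter", min = 1)
  stop_if_not_scalar_number(tol, "tol", min = 0, strict_min = TRUE)
  if (!is.null(bias_smooth_sigma)) {
    stop_if_not_scalar_number(bias_smooth_sigma, "bias_smooth_sigma",
                              min = 0, strict_min = TRUE)
  }
  if (length(bias_clamp) != 2 || any(bias_clamp <= 0) ||
      bias_clamp[1] > bias_clamp[2]) {
    abort("`bias_clamp` must be two positive ordered numbers.",
          class = "airspace_error_validation")
  }
  structure(list(m = m, max_iter = max_iter, tol = tol,
                 bias_smooth_sigma = bias_smooth_sigma,
                 bias_clamp = bias_clamp),
            class = "fcm_params")
}

#' Fuzzy c-means clustering with multiplicative bias-field correction
#'
#' Two-class fuzzy c-means on pixel intensities with simultaneous correction
#' of luminance inhomogeneity. The model is a smooth multiplicative field
#' `b` distorting two class centroids `v`, fit by alternating minimisation
#' of
#' \deqn{J = \sum_{p} \sum_{k} u_{pk}^m (x_p - b_p v_k)^2}
#' with the standard membership and centroid updates, followed by a bias
#' re-estimate: the ratio of observed to reconstructed intensity, Gaussian
#' smoothed at `bias_smooth_sigma` and clamped to `bias_clamp`.
#'
#' Initialisation is deterministic — centroids start at the 25th and 75th
#' intensity percentiles and the bias field at 1 — so the result depends
#' only on the image and the parameters, never on a random seed. Iteration
#' stops when the largest membership change falls below `tol` or after
#' `max_iter` updates (in which case the result carries
#' `converged = FALSE` and a warning is issued).
#'
#' @param image A [calibrated_image()]; must not be constant.
#' @param params An [fcm_params()] list.
#' @return An object of class `membership_field`: list with `u` (H x W x 2
#'   membership array summing to 1 per pixel; class 2 is the brighter
#'   class), `v` (centroids, ascending), `b` (bias field, > 0), `n_iter`,
#'   `converged`, and `objective` (the trace of J).
#' @export
fcm_bias <- function(image, params = fcm_params()) {
  stopifnot(inherits(image, "calibrated_image"))
  x <- image$pixels
  if (diff(range(x)) == 0) {
    abort("Image is constant; two-class clustering is undefined.",
          class = "airspace_error_degenerate_image")
  }
  h <- nrow(x); w <- ncol(x)
  sigma <- params$bias_smooth_sigma %||% (min(h, w) / 4)
  m <- params$m
  pw <- 1 / (m - 1)
  eps <- 1e-12

  v <- sort(unname(quantile(x, c(0.25, 0.75))))
  if (v[1] == v[2]) v <- range(x)
  b <- matrix(1, h, w)
  u1 <- matrix(0.5, h, w)
  obj <- numeric(0)

  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    d1 <- (x - b * v[1])^2
    d2 <- (x - b * v[2])^2
    # membership update; exact centroid hits get full membership
    w1 <- (pmax(d1, eps))^(-pw)
    w2 <- (pmax(d2, eps))^(-pw)
    u1_new <- w1 / (w1 + w2)
    delta <- max(abs(u1_new - u1))
    u1 <- u1_new
    u2 <- 1 - u1

    um1 <- u1^m
    um2 <- u2^m
    v[1] <- sum(um1 * b * x) / sum(um1 * b^2)
    v[2] <- sum(um2 * b * x) / sum(um2 * b^2)
    if (v[1] > v[2]) {  # keep class 2 the brighter one
      v <- rev(v)
      tmp <- u1; u1 <- u2; u2 <- tmp
      tmp <- um1; um1 <- um2; um2 <- tmp
    }

    recon <- (um1 * v[1] + um2 * v[2]) / (um1 + um2)
    ratio <- x / pmax(recon, eps)
    b <- gaussian_smooth(ratio, sigma)
    b <- pmin(pmax(b, params$bias_clamp[1]), params$bias_clamp[2])

    obj <- c(obj, sum(um1 * (x - b * v[1])^2) + sum(um2 * (x - b * v[2])^2))
    if (delta < params$tol) { converged <- TRUE; break }
    if (it >= params$max_iter) break
  }
  if (!converged) {
    warn(sprintf("fcm_bias did not converge in %d iterations (last delta %.2g).",
                 it, delta))
  }
  u <- array(c(u1, 1 - u1), c(h, w, 2))
  structure(list(u = u, v = v, b = b, n_iter = it, converged = converged,
                 objective = obj, px_size_um = image$px_size_um),
            class = "membership_field")
}

#' @export
print.membership_field <- function(x, ...) {
  cat(sprintf(
    "<membership_field> %d x %d px, centroids [%.3f, %.3f], %d iteration%s%s\n",
    dim(x$u)[1], dim(x$u)[2], x$v[1], x$v[2], x$n_iter,
    if (x$n_iter == 1) "" else "s",
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
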