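# Internal validation and numeric helpers.

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "airspace_error_validation")
  }
  low_ok <- if (strict_min) x > min else x >= min
  if (!low_ok || x > max) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x),
          class = "airspace_error_validation")
  }
  invisible(x)
}

stop_if_not_probability <- function(x, name) {
  stop_if_not_scalar_number(x, name, min = 0, max = 1)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices (or vectors) of equal size.
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (length(a) != length(b)) {
    abort("Masks must have the same number of pixels.",
          class = "airspace_error_validation")
  }
  a <- as.logical(a)
  b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Large-kernel Gaussian smoothing of a matrix, used for bias-field
# re-estimation.  For sigma beyond a few pixels the matrix is block-mean
# downsampled, blurred with an equivalent small kernel, and upsampled
# bilinearly; edges are handled by replication.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  f <- max(1L, as.integer(floor(sigma / 4)))
  f <- min(f, nrow(m), ncol(m))
  small <- if (f > 1L) block_mean(m, f) else m
  blurred <- separable_gaussian(small, sigma / f)
  if (f > 1L) bilinear_upsample(blurred, nrow(m), ncol(m), f) else blurred
}

block_mean <- function(m, f) {
  h2 <- ceiling(nrow(m) / f) * f
  w2 <- ceiling(ncol(m) / f) * f
  mp <- m[pmin(seq_len(h2), nrow(m)), pmin(seq_len(w2), ncol(m)), drop = FALSE]
  a <- array(mp, c(f, h2 / f, f, w2 / f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

separable_gaussian <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  m <- blur_rows(m, k, r)
  t(blur_rows(t(m), k, r))
}

blur_rows <- function(m, k, r) {
  h <- nrow(m)
  out <- matrix(0, h, ncol(m))
  for (i in seq_along(k)) {
    src <- pmin(pmax(seq_len(h) + (i - r - 1L), 1L), h)  # replicated edges
    out <- out + k[i] * m[src, , drop = FALSE]
  }
  out
}

bilinear_upsample <- function(s, h, w, f) {
  ri <- pmin(pmax((seq_len(h) - 0.5) / f + 0.5, 1), nrow(s))
  ci <- pmin(pmax((seq_len(w) - 0.5) / f + 0.5, 1), ncol(s))
  r0 <- pmin(floor(ri), nrow(s) - 1e-9)
  c0 <- pmin(floor(ci), ncol(s) - 1e-9)
  r0i <- as.integer(r0); r1i <- pmin(r0i + 1L, nrow(s))
  c0i <- as.integer(c0); c1i <- pmin(c0i + 1L, ncol(s))
  fr <- matrix(ri - r0i, h, w)
  fc <- matrix(ci - c0i, h, w, byrow = TRUE)
  (1 - fr) * (1 - fc) * s[r0i, c0i, drop = FALSE] +
    fr * (1 - fc) * s[r1i, c0i, drop = FALSE] +
    (1 - fr) * fc * s[r0i, c1i, drop = FALSE] +
    fr * fc * s[r1i, c1i, drop = FALSE]
}

# 4-connected grid edge list (0-based, for the compiled min-cut).
grid_edges_4 <- function(h, w) {
  idx <- matrix(0:(h * w - 1L), h, w)
  u <- c(as.vector(idx[, -w, drop = FALSE]), as.vector(idx[-h, , drop = FALSE]))
  v <- c(as.vector(idx[, -1, drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  cbind(u = u, v = v)
}
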