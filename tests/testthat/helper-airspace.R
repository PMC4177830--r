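# Build a membership_field by hand for graph-cut tests: u1 in (0, 1) gives
# the tissue-class membership, class 2 (airspace) gets 1 - u1.
make_field <- function(u1, v = c(0.3, 0.8)) {
  h <- nrow(u1); w <- ncol(u1)
  structure(list(u = array(c(u1, 1 - u1), c(h, w, 2)), v = v,
                 b = matrix(1, h, w), n_iter = 1L, converged = TRUE,
                 objective = numeric(0), px_size_um = 1),
            class = "membership_field")
}

# Exhaustive minimum of the Potts energy over all 2^(h*w) labelings.
brute_force_min_energy <- function(field, image, params) {
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  n <- h * w
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- matrix(as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L)), h, w)
    e <- graph_cut_energy(lab, field, image, params)
    if (e < best) best <- e
  }
  best
}

# A small two-class image with known ground truth: a bright rectangle on a
# dark background plus deterministic "noise" from a seeded draw.
tiny_two_class_image <- function(h = 32, w = 32, seed = 1) {
  truth <- matrix(FALSE, h, w)
  truth[8:24, 10:28] <- TRUE
  withr::with_seed(seed, {
    px <- 0.4 + 0.4 * truth + matrix(rnorm(h * w, 0, 0.03), h, w)
  })
  list(image = calibrated_image(pmin(pmax(px, 0), 1), px_size_um = 2),
       truth = truth)
}

# Rasterise disjoint discs the same way the generator does, returning the
# mask and the planted equivalent diameters (in um at px_size_um = 1).
disjoint_disc_mask <- function(size, centers, radii_px) {
  mask <- matrix(FALSE, size, size)
  for (i in seq_along(radii_px)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii_px[i]
    rr <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
    cc <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
    inside <- outer((rr - cy)^2, (cc - cx)^2, `+`) <= r^2
    mask[rr, cc] <- mask[rr, cc] | inside
  }
  mask
}
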