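test_that("label_compartments finds hand-constructed components", {
  m <- matrix(FALSE, 5, 6)
  m[2:3, 2:3] <- TRUE          # interior 4-px square
  m[5, 5:6] <- TRUE            # 2-px component on the border
  m[1, 1] <- TRUE              # single corner pixel
  cs <- label_compartments(m, morphometry_params(), px_size_um = 10)
  expect_s3_class(cs, "compartment_set")
  expect_equal(nrow(cs), 3)
  expect_setequal(cs$n_px, c(4L, 2L, 1L))
  expect_equal(cs$area_um2, cs$n_px * 100)
  expect_equal(cs$diameter_um, 2 * sqrt(cs$area_um2 / pi))
  expect_equal(sum(cs$touches_border), 2)  # the corner and the bottom pair
  expect_false(cs$touches_border[cs$n_px == 4])
})

test_that("4- vs 8-connectivity splits or joins diagonal pixels", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE
  cs4 <- label_compartments(m, morphometry_params(connectivity = 4),
                            px_size_um = 1)
  cs8 <- label_compartments(m, morphometry_params(connectivity = 8),
                            px_size_um = 1)
  expect_equal(nrow(cs4), 2)
  expect_equal(nrow(cs8), 1)
})

test_that("empty masks and bare-matrix input are handled", {
  cs <- label_compartments(matrix(FALSE, 3, 3), px_size_um = 1)
  expect_equal(nrow(cs), 0)
  expect_error(label_compartments(matrix(TRUE, 3, 3)),
               class = "airspace_error_validation")
  expect_error(morphometry_params(connectivity = 6),
               class = "airspace_error_validation")
})

test_that("filter_compartments keeps the threshold itself and drops borders", {
  # three interior compartments with diameters straddling the threshold
  cs <- label_compartments(matrix(FALSE, 3, 3), px_size_um = 1)
  fake <- tibble::tibble(compartment = 1:4, n_px = 1L,
                         area_um2 = 1,
                         diameter_um = c(100, 138, 200, 300),
                         touches_border = c(FALSE, FALSE, FALSE, TRUE))
  attr(fake, "params") <- morphometry_params()
  class(fake) <- class(cs)
  d <- filter_compartments(fake)
  expect_equal(as.numeric(d), c(138, 200))  # >= 138 kept, border dropped
  expect_equal(attr(d, "n_kept"), 2L)
  expect_equal(attr(d, "n_removed"), 1L)
  expect_equal(attr(d, "n_border_excluded"), 1L)
  d2 <- filter_compartments(fake, min_diameter_um = 0)
  expect_equal(length(d2), 3)
  expect_error(filter_compartments(fake, min_diameter_um = -1),
               class = "airspace_error_validation")
})

test_that("D-index hand oracles hold exactly", {
  expect_equal(d_index(c(100, 200), k = 2)$value_um, 180)
  expect_equal(d_index(c(150, 200), k = 2)$value_um, 182)
  expect_equal(d_index(c(3, 5, 9), k = 0)$value_um, mean(c(3, 5, 9)))
  r <- d_index(c(100, 200))
  expect_s3_class(r, "dindex_result")
  expect_equal(r$n_compartments_used, 2)
  expect_output(print(r), "D_2 = 180.00 um")
  expect_equal(tidy(r)$value_um, 180)
})

test_that("D-index is monotone in k, scale-equivariant and bounded", {
  set.seed(21)
  for (i in 1:200) {
    d <- rlnorm(sample(2:40, 1), log(100), 0.6)
    v <- vapply(0:4, function(k) d_index(d, k)$value_um, numeric(1))
    expect_true(all(diff(v) >= -1e-9))
    expect_lte(v[5], max(d) + 1e-9)
    expect_gte(v[1], min(d) - 1e-9)
    s <- runif(1, 0.1, 10)
    expect_equal(d_index(s * d, k = 2)$value_um,
                 s * d_index(d, k = 2)$value_um, tolerance = 1e-10)
  }
})

test_that("D-index rejects empty and invalid input", {
  expect_error(d_index(numeric(0)),
               class = "airspace_error_empty_compartments")
  expect_error(d_index(c(100, -5)), class = "airspace_error_validation")
  expect_error(d_index(c(100, Inf)), class = "airspace_error_validation")
  expect_error(d_index(c(100, 200), k = -1),
               class = "airspace_error_validation")
})

test_that("d_index_from_mask equals the manual composition", {
  sp <- histology_sim_params(width_px = 96, height_px = 96, px_size_um = 16,
                             seed = 2)
  mask <- generate_alveolar_image(sp)$ground_truth$mask
  manual <- d_index(filter_compartments(
    label_compartments(mask, px_size_um = 16)))
  auto <- d_index_from_mask(mask, px_size_um = 16)
  expect_equal(auto$value_um, manual$value_um)
  expect_equal(auto$n_compartments_used, manual$n_compartments_used)
})

test_that("D2 of rasterised disjoint discs matches the planted value", {
  # planted diameters in px (px_size_um = 1); centers far apart and off-border
  diam <- c(30, 44, 58, 72, 86)
  centers <- cbind(c(60, 60, 170, 170, 280), c(60, 200, 60, 240, 150))
  mask <- disjoint_disc_mask(340, centers, diam / 2)
  planted <- d_index(diam, k = 2)$value_um
  got <- d_index_from_mask(mask, morphometry_params(min_diameter_um = 0),
                           px_size_um = 1)
  expect_equal(got$n_compartments_used, length(diam))
  expect_lt(abs(got$value_um - planted) / planted, 0.05)
})
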