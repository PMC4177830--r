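test_that("graph_cut_refine attains the exhaustive minimum on small grids", {
  set.seed(11)
  for (dims in list(c(3, 3), c(3, 4))) {
    for (rep in 1:3) {
      h <- dims[1]; w <- dims[2]
      u1 <- matrix(runif(h * w, 0.05, 0.95), h, w)
      field <- make_field(u1)
      image <- calibrated_image(matrix(runif(h * w), h, w), 1)
      for (lambda in c(0, 0.5, 5)) {
        params <- graph_cut_params(lambda = lambda)
        mask <- graph_cut_refine(field, image, params)
        expect_equal(attr(mask, "energy"),
                     brute_force_min_energy(field, image, params),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("lambda = 0 reduces to per-pixel argmax memberships", {
  set.seed(5)
  u1 <- matrix(runif(20, 0.05, 0.95), 4, 5)
  field <- make_field(u1)
  image <- calibrated_image(matrix(runif(20), 4, 5), 1)
  mask <- graph_cut_refine(field, image, graph_cut_params(lambda = 0))
  expect_identical(mask$mask, u1 < 0.5)  # airspace = class 2 = 1 - u1 > u1
  expect_equal(attr(mask, "energy"), attr(mask, "energy_argmax"))
})

test_that("refined energy never exceeds the argmax labeling energy", {
  set.seed(9)
  u1 <- matrix(runif(100, 0.05, 0.95), 10, 10)
  field <- make_field(u1)
  image <- calibrated_image(matrix(runif(100), 10, 10), 1)
  for (lambda in c(0.2, 1, 4)) {
    mask <- graph_cut_refine(field, image, graph_cut_params(lambda = lambda))
    expect_lte(attr(mask, "energy"), attr(mask, "energy_argmax") + 1e-12)
  }
})

test_that("a dominant pairwise term forces a constant labeling", {
  set.seed(3)
  u1 <- matrix(runif(36, 0.3, 0.7), 6, 6)
  field <- make_field(u1)
  image <- calibrated_image(matrix(0.5, 6, 6) + matrix(rnorm(36, 0, 1e-3), 6, 6), 1)
  mask <- graph_cut_refine(field, image, graph_cut_params(lambda = 1e4))
  expect_true(all(mask$mask) || !any(mask$mask))
})

test_that("airspace_class = 'dark' flips which centroid counts as airspace", {
  u1 <- matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2)
  field <- make_field(u1)
  image <- calibrated_image(matrix(c(0.2, 0.2, 0.9, 0.9), 2, 2), 1)
  bright <- graph_cut_refine(field, image, graph_cut_params(lambda = 0))
  dark <- graph_cut_refine(field, image,
                           graph_cut_params(lambda = 0, airspace_class = "dark"))
  expect_identical(bright$mask, !dark$mask)
})

test_that("graph_cut_energy scores arbitrary labelings consistently", {
  u1 <- matrix(c(0.8, 0.2, 0.6, 0.4), 2, 2)
  field <- make_field(u1)
  image <- calibrated_image(matrix(c(0.1, 0.9, 0.3, 0.7), 2, 2), 1)
  params <- graph_cut_params(lambda = 1, sigma_i = 1, epsilon = 1e-6)
  lab <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  # hand computation: unary -log of the labeled class membership, plus the
  # contrast weight on each cut 4-neighbour edge; rows are constant under
  # this labeling, so only the two vertical edges are cut
  unary <- -log(c(1 - 0.8, 0.2, 1 - 0.6, 0.4))
  x <- image$pixels
  edges <- rbind(c(x[1, 1], x[1, 2]), c(x[2, 1], x[2, 2]),  # horizontal
                 c(x[1, 1], x[2, 1]), c(x[1, 2], x[2, 2]))  # vertical
  cut <- c(FALSE, FALSE, TRUE, TRUE)
  w <- exp(-(edges[, 1] - edges[, 2])^2 / 2)
  expect_equal(graph_cut_energy(lab, field, image, params),
               sum(unary) + sum(w[cut]))
})

test_that("graph-cut parameter and shape validation", {
  expect_error(graph_cut_params(lambda = -1), class = "airspace_error_validation")
  expect_error(graph_cut_params(epsilon = 0), class = "airspace_error_validation")
  expect_error(graph_cut_params(epsilon = 1), class = "airspace_error_validation")
  field <- make_field(matrix(0.5, 2, 2))
  image <- calibrated_image(matrix(0.5, 3, 3), 1)
  expect_error(graph_cut_refine(field, image),
               class = "airspace_error_validation")
})

test_that("airspace_mask validates and prints", {
  expect_error(airspace_mask(1:4, 1), class = "airspace_error_validation")
  expect_error(airspace_mask(matrix(TRUE, 2, 2), 0),
               class = "airspace_error_validation")
  m <- airspace_mask(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2), 2)
  expect_output(print(m), "airspace fraction 0.500")
})
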