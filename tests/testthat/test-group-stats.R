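test_that("Mann-Whitney hand oracle: U = 0, exact p = 0.1", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_true(r$exact)
})

test_that("Mann-Whitney full-tie and symmetry properties", {
  r <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$statistic, 9 / 2)
  expect_equal(r$p_value, 1)
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    r1 <- mann_whitney(a, b); r2 <- mann_whitney(b, a)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$statistic, r2$statistic)
  }
})

test_that("exact Mann-Whitney matches wilcox.test on untied data", {
  set.seed(8)
  for (i in 1:30) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    want <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(mann_whitney(a, b, exact = TRUE)$p_value, want,
                 tolerance = 1e-12)
  }
})

test_that("asymptotic Mann-Whitney matches wilcox.test with correction", {
  set.seed(12)
  for (i in 1:30) {
    a <- rnorm(25); b <- rnorm(30, 0.3)
    want <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(mann_whitney(a, b, exact = FALSE)$p_value, want,
                 tolerance = 1e-12)
  }
})

test_that("enumeration and asymptotic p agree within 0.02 at the boundary", {
  # exhaustive over every attainable U at the n1 = n2 = 8 boundary (untied)
  a_ranks <- 1:16
  u_null <- {
    cmb <- combn(16, 8)
    u1 <- colSums(matrix(a_ranks[cmb], nrow = 8)) - 8 * 9 / 2
    pmin(u1, 64 - u1)
  }
  for (u in 0:32) {
    p_exact <- mean(u_null <= u + 1e-9)
    dev <- u - 32
    z <- sign(dev) * max(abs(dev) - 0.5, 0) / sqrt(8 * 8 * 17 / 12)
    p_asym <- min(1, 2 * pnorm(-abs(z)))
    expect_lte(abs(p_exact - p_asym), 0.02)
  }
  # and on random continuous draws through the public interface
  set.seed(2)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(8, runif(1, -1, 1))
    d <- abs(mann_whitney(a, b, exact = TRUE)$p_value -
             mann_whitney(a, b, exact = FALSE)$p_value)
    expect_lte(d, 0.02)
  }
})

test_that("Kruskal-Wallis hand oracle and tie behaviour", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)  # 4.571
  expect_equal(r$p_value, pchisq(32 / 7, 2, lower.tail = FALSE))
  allsame <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(allsame$statistic, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("Kruskal-Wallis matches kruskal.test including ties", {
  set.seed(6)
  for (i in 1:20) {
    g <- list(round(rnorm(7), 1), round(rnorm(6, 0.4), 1), round(rnorm(8), 1))
    want <- kruskal.test(g)
    r <- kruskal_wallis(g)
    expect_equal(r$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("Kolmogorov-Smirnov statistic and p match ks.test", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(6, 0.8)
    want <- suppressWarnings(ks.test(a, b, exact = TRUE))
    r <- ks_two_sample(a, b, exact = TRUE)
    expect_equal(r$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, unname(want$p.value), tolerance = 1e-12)
  }
  a <- rnorm(40); b <- rnorm(45, 0.5)
  want <- suppressWarnings(ks.test(a, b, exact = FALSE))
  r <- ks_two_sample(a, b, exact = FALSE)
  expect_equal(r$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, unname(want$p.value), tolerance = 1e-4)
})

test_that("validation errors for degenerate test input", {
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "airspace_error_validation")
  expect_error(mann_whitney(c(1, NA), 1:3),
               class = "airspace_error_validation")
  expect_error(kruskal_wallis(list(1:3)), class = "airspace_error_validation")
  expect_error(kruskal_wallis(1:3), class = "airspace_error_validation")
  expect_error(ks_two_sample(1:3, numeric(0)),
               class = "airspace_error_validation")
})

test_that("compare_genotype_groups reports omnibus plus all pairs", {
  d <- tibble::tibble(
    group = rep(c("wt", "het", "hom"), each = 4),
    d2_um = c(100, 110, 105, 95, 140, 150, 145, 155, 200, 210, 220, 190))
  rep3 <- compare_genotype_groups(d)
  expect_equal(nrow(rep3), 1 + 3)
  expect_equal(rep3$test[1], "Kruskal-Wallis")
  expect_true(all(rep3$test[-1] == "Mann-Whitney U"))
  expect_true(all(c("statistic", "p_value", "exact", "significant") %in%
                    names(rep3)))
  # invariant to relabeling group names
  d2 <- d; d2$group <- toupper(d2$group)
  rep3b <- compare_genotype_groups(d2)
  expect_equal(sort(rep3$p_value), sort(rep3b$p_value))
  expect_error(compare_genotype_groups(d[d$group == "wt", ]),
               class = "airspace_error_validation")
})

test_that("omnibus p-values are uniform under the null", {
  set.seed(14)
  ps <- replicate(500, {
    d <- tibble::tibble(group = rep(c("a", "b"), each = 25),
                        d2_um = rlnorm(50, log(300), 0.3))
    compare_genotype_groups(d)$p_value[1]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("htest print and tidy methods work", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_output(print(r), "Mann-Whitney U")
  td <- tidy(r)
  expect_equal(td$p_value, 0.1)
  expect_equal(td$n, "3,3")
})
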