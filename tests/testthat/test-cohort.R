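test_that("classify_gold implements the spirometry thresholds exactly", {
  got <- classify_gold(
    fev1_fvc_ratio = c(0.80, 0.70, 0.699, 0.65, 0.60, 0.50, 0.45),
    fev1_pct_pred  = c(90,   90,   81,    80,   50,   49.9, 30))
  expect_equal(as.character(got),
               c("none", "none", "I", "II", "II", "III/IV", "III/IV"))
  expect_equal(levels(got), c("none", "I", "II", "III/IV"))
})

test_that("classify_gold handles missing and invalid spirometry", {
  expect_error(classify_gold(c(0.6, NA), c(70, 80)),
               class = "airspace_error_not_classifiable")
  got <- classify_gold(c(0.6, NA), c(70, 80), incomplete = "na")
  expect_equal(as.character(got), c("II", NA))
  expect_error(classify_gold(0.6, -5), class = "airspace_error_validation")
  expect_error(classify_gold(1.7, 90), class = "airspace_error_validation")
  expect_error(classify_gold(c(0.6, 0.7), 90),
               class = "airspace_error_validation")
})

test_that("summarize_table1 formats binary and continuous covariates", {
  d <- tibble::tibble(
    group = rep(c("AA", "AOD"), c(4, 5)),
    male = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    age = c(70, 72, 68, 74, 60, 62, 58, 64, 66))
  tb <- summarize_table1(d)
  male_aa <- tb[tb$variable == "male" & tb$group == "AA", ]
  expect_equal(male_aa$count, 3)
  expect_equal(male_aa$percent, 75)
  expect_equal(male_aa$summary, "3 (75.0)")
  age_aod <- tb[tb$variable == "age" & tb$group == "AOD", ]
  expect_equal(age_aod$mean, 62)
  expect_match(age_aod$summary, "^62.0±")
  expect_error(summarize_table1(d[0, ]), class = "airspace_error_validation")
})

test_that("prevalence_chi_square matches the uncorrected Pearson test", {
  tab <- matrix(c(258, 203, 356, 576), 2, 2)
  got <- prevalence_chi_square(tab)
  want <- chisq.test(tab, correct = FALSE)
  expect_equal(got$result$statistic, unname(want$statistic))
  expect_equal(got$result$p_value, unname(want$p.value))
  expect_output(print(got), "chi-square")
})

test_that("prevalence_chi_square data-frame interface and degeneracy", {
  d <- tibble::tibble(copd = rep(c(TRUE, FALSE), c(30, 70)),
                      group = rep(c("AA", "AOD"), 50))
  got <- prevalence_chi_square(d)
  expect_equal(sum(got$table), 100)
  expect_error(prevalence_chi_square(matrix(c(0, 0, 5, 5), 2, 2)),
               class = "airspace_error_validation")
  expect_error(prevalence_chi_square(matrix(1:6, 2, 3)),
               class = "airspace_error_validation")
  d$copd <- TRUE
  expect_error(prevalence_chi_square(d), class = "airspace_error_validation")
})

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  counts <- matrix(c(258, 203, 356, 576), 2, 2,
                   dimnames = list(c("copd", "no"), c("AA", "AOD")))
  d <- tibble::tibble(
    copd = rep(c(TRUE, FALSE, TRUE, FALSE), counts),
    group = factor(rep(c("AA", "AA", "AOD", "AOD"), counts),
                   levels = c("AOD", "AA")))
  fit <- logistic_fit(d)
  cross <- (258 * 576) / (356 * 203)
  expect_equal(fit$odds_ratio, cross, tolerance = 1e-6)
  expect_false(fit$adjusted)
  expect_output(print(fit), "OR")
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n, sum(counts))
  expect_true(gl$converged)
})

test_that("logistic_fit raises on separation and bad outcomes", {
  d <- tibble::tibble(copd = rep(c(TRUE, FALSE), each = 20),
                      x = rep(c(1, 0), each = 20))
  expect_error(logistic_fit(d, predictors = "x"),
               class = "airspace_error_separation")
  expect_error(logistic_fit(tibble::tibble(copd = rep(TRUE, 5), x = 1:5),
                            predictors = "x"),
               class = "airspace_error_validation")
})

test_that("propensity adjustment adds the score, degenerates gracefully", {
  co <- generate_cohort(cohort_sim_params(n_patients = 3000, seed = 5))
  fit <- propensity_covariate_fit(co, score_covariates = c("age", "gender_male"))
  expect_true(".propensity_score" %in% fit$terms)
  expect_true(fit$adjusted)
  co$spirometry_available <- TRUE
  expect_warning(fit2 <- propensity_covariate_fit(
    co, score_covariates = c("age", "gender_male")), "constant")
  expect_false(fit2$adjusted)
  expect_match(fit2$note, "degenerate")
  co$spirometry_available <- NULL
  expect_error(propensity_covariate_fit(co),
               class = "airspace_error_validation")
})

test_that("copd_assoc autoplot returns a ggplot", {
  co <- generate_cohort(cohort_sim_params(n_patients = 800, seed = 2))
  p <- ggplot2::autoplot(logistic_fit(co))
  expect_s3_class(p, "ggplot")
})
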