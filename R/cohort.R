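#' GOLD classification from spirometry
#'
#' COPD is present when the FEV1/FVC ratio is strictly below 0.70. Among
#' COPD cases the severity grade follows the percent-of-predicted FEV1:
#' above 80 percent is GOLD I (mild), 50 to 80 percent inclusive is GOLD II
#' (moderate), below 50 percent is GOLD III/IV (severe). A ratio of exactly
#' 0.70 is not COPD, and FEV1 of exactly 80 or 50 percent falls in GOLD II.
#'
#' @param fev1_fvc_ratio FEV1/FVC ratio(s), in (0, 1.5].
#' @param fev1_pct_pred FEV1 as percent of predicted.
#' @param incomplete What to do with missing spirometry: `"error"` (default)
#'   signals that the record is not classifiable; `"na"` returns `NA` so a
#'   caller can apply its own fallback (e.g. a symptom-based flag).
#' @return Factor with levels `none`, `I`, `II`, `III/IV`.
#' @export
classify_gold <- function(fev1_fvc_ratio, fev1_pct_pred,
                          incomplete = c("error", "na")) {
  incomplete <- match.arg(incomplete)
  if (length(fev1_fvc_ratio) != length(fev1_pct_pred)) {
    abort("Spirometry vectors must have equal length.",
          class = "airspace_error_validation")
  }
  missing <- is.na(fev1_fvc_ratio) | is.na(fev1_pct_pred)
  if (any(missing) && incomplete == "error") {
    abort(sprintf("%d record(s) without spirometry are not classifiable.",
                  sum(missing)),
          class = "airspace_error_not_classifiable")
  }
  ok <- !missing
  if (any(fev1_fvc_ratio[ok] <= 0 | fev1_fvc_ratio[ok] > 1.5 |
          fev1_pct_pred[ok] <= 0)) {
    abort("Spirometry values out of range (ratio in (0, 1.5], FEV1% > 0).",
          class = "airspace_error_validation")
  }
  out <- rep(NA_character_, length(fev1_fvc_ratio))
  copd <- ok & fev1_fvc_ratio < 0.70
  out[ok & !copd] <- "none"
  out[copd & fev1_pct_pred > 80] <- "I"
  out[copd & fev1_pct_pred >= 50 & fev1_pct_pred <= 80] <- "II"
  out[copd & fev1_pct_pred < 50] <- "III/IV"
  factor(out, levels = c("none", "I", "II", "III/IV"))
}

#' Baseline characteristics table by group
#'
#' Summarises a patient table the way clinical baseline tables are printed:
#' logical (or 0/1) covariates as count and percent of the group
#' (`100 * count / group_n`, rounded to one decimal), continuous covariates
#' as mean and standard deviation to one decimal.
#'
#' @param data Patient data frame.
#' @param group Grouping column, unquoted (default `group`).
#' @return A tibble with `variable`, `group`, `n`, `count`, `percent`,
#'   `mean`, `sd` and a formatted `summary` string.
#' @export
summarize_table1 <- function(data, group = group) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    abort("Patient table is empty.", class = "airspace_error_validation")
  }
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  gq <- rlang::as_name(rlang::enquo(group))
  if (any(table(g) == 0) || length(unique(g)) < 1) {
    abort("Every group must be non-empty.", class = "airspace_error_validation")
  }
  vars <- setdiff(names(data), gq)
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    is_binary <- is.logical(x) ||
      (is.numeric(x) && all(x %in% c(0, 1, NA)))
    if (!is_binary && !is.numeric(x)) next
    for (lev in unique(g)) {
      xi <- x[g == lev]
      n <- sum(!is.na(xi))
      if (n == 0) {
        abort(sprintf("Group '%s' has no data for '%s'.", lev, v),
              class = "airspace_error_validation")
      }
      if (is_binary) {
        cnt <- sum(xi, na.rm = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, group = lev, n = n, count = cnt,
          percent = round(100 * cnt / n, 1), mean = NA_real_, sd = NA_real_,
          summary = sprintf("%d (%.1f)", cnt, round(100 * cnt / n, 1)))
      } else {
        mu <- mean(xi, na.rm = TRUE); s <- sd(xi, na.rm = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, group = lev, n = n, count = NA_integer_,
          percent = NA_real_, mean = round(mu, 1), sd = round(s, 1),
          summary = sprintf("%.1f±%.1f", mu, s))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' COPD-by-group contingency table and chi-square test
#'
#' Pearson chi-square without continuity correction on the 2 x 2 table of a
#' binary outcome against a two-level group.
#'
#' @param data A patient data frame, or a 2 x 2 numeric matrix of counts
#'   (rows = outcome, columns = group).
#' @param outcome,group Columns, unquoted (defaults `copd`, `group`); ignored
#'   for matrix input.
#' @return List of class `prevalence_test` with `table` (2 x 2 counts) and
#'   `result` (an `airspace_htest`).
#' @export
prevalence_chi_square <- function(data, outcome = copd, group = group) {
  if (is.matrix(data)) {
    tab <- data
    if (!all(dim(tab) == c(2, 2))) {
      abort("Count matrix must be 2 x 2.", class = "airspace_error_validation")
    }
  } else {
    o <- rlang::eval_tidy(rlang::enquo(outcome), data)
    g <- rlang::eval_tidy(rlang::enquo(group), data)
    tab <- table(factor(o), factor(g))
    if (!all(dim(tab) == c(2, 2))) {
      abort("Outcome and group must each have exactly two levels present.",
            class = "airspace_error_validation")
    }
    tab <- unclass(tab)
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    which_m <- c(paste0("row ", which(rs == 0)), paste0("column ", which(cs == 0)))
    abort(sprintf("Degenerate margin (%s) in the 2 x 2 table.",
                  paste(which_m[which_m != ""], collapse = ", ")),
          class = "airspace_error_validation")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- new_htest("Pearson chi-square (df = 1)",
                   unname(ct$statistic), unname(ct$p.value), FALSE, sum(tab))
  structure(list(table = tab, result = res), class = "prevalence_test")
}

#' @export
print.prevalence_test <- function(x, ...) {
  print(x$table)
  print(x$result)
  invisible(x)
}

new_assoc_result <- function(fit, exposure_term, adjusted, note = NULL) {
  est <- coef(summary(fit))
  if (!exposure_term %in% rownames(est)) {
    # factor exposures get level-suffixed coefficient names
    hit <- grep(paste0("^", exposure_term), rownames(est), value = TRUE)
    if (length(hit) == 0) {
      abort(sprintf("Exposure term '%s' not found in the fit.", exposure_term),
            class = "airspace_error_validation")
    }
    exposure_term <- hit[1]
  }
  b <- est[exposure_term, "Estimate"]
  se <- est[exposure_term, "Std. Error"]
  structure(list(
    fit = fit, term = exposure_term,
    odds_ratio = exp(b),
    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    p_value = est[exposure_term, "Pr(>|z|)"],
    terms = rownames(est), n = length(fit$y),
    converged = fit$converged, adjusted = adjusted, note = note),
    class = "copd_assoc")
}

#' @export
print.copd_assoc <- function(x, ...) {
  cat(sprintf("%s: OR %.3f, 95%% CI %.3f-%.3f, p = %.3g (n = %d%s)\n",
              x$term, x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$n,
              if (x$converged) "" else ", NOT converged"))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
tidy.copd_assoc <- function(x, ...) {
  est <- coef(summary(x$fit))
  tibble::tibble(term = rownames(est),
                 estimate = est[, "Estimate"],
                 std_error = est[, "Std. Error"],
                 odds_ratio = exp(est[, "Estimate"]),
                 ci_low = exp(est[, "Estimate"] - 1.96 * est[, "Std. Error"]),
                 ci_high = exp(est[, "Estimate"] + 1.96 * est[, "Std. Error"]),
                 p_value = est[, "Pr(>|z|)"])
}

#' @export
glance.copd_assoc <- function(x, ...) {
  tibble::tibble(n = x$n, converged = x$converged, adjusted = x$adjusted,
                 deviance = x$fit$deviance, df_residual = x$fit$df.residual)
}

#' @export
autoplot.copd_assoc <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% Wald CI)", y = NULL)
}

#' Logistic odds-ratio fit for a binary outcome
#'
#' Maximum-likelihood binary logistic regression (IRLS via [stats::glm()])
#' of an outcome on an exposure and optional covariates. The association is
#' reported as the exposure odds ratio `exp(coef)` with a 95 percent Wald
#' interval `exp(coef +- 1.96 SE)`. Complete or quasi-complete separation
#' (any coefficient beyond 15 on the log-odds scale) raises an error;
#' non-convergence is returned flagged, not raised.
#'
#' @param data Patient data frame.
#' @param outcome Name of the binary outcome column (default `"copd"`).
#' @param predictors Character vector of predictor columns; the first is the
#'   exposure whose odds ratio is headlined (default `"group"`).
#' @return A `copd_assoc` object (see [tidy()] / [glance()] methods).
#' @export
logistic_fit <- function(data, outcome = "copd", predictors = "group") {
  stopifnot(is.data.frame(data), length(predictors) >= 1)
  y <- data[[outcome]]
  if (is.null(y) || length(unique(y[!is.na(y)])) != 2) {
    abort("Outcome must exist and take exactly two values.",
          class = "airspace_error_validation")
  }
  f <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(
    glm(f, family = binomial(), data = data,
        control = glm.control(epsilon = 1e-10, maxit = 50)))
  # separation: a coefficient diverging beyond 15 log-odds across the
  # observed range of its predictor (plain |coef| would flag legitimate
  # large slopes on near-constant covariates such as propensity scores)
  mm <- stats::model.matrix(fit)
  cf <- coef(fit)[-1]
  spread <- apply(mm[, -1, drop = FALSE], 2, function(x) diff(range(x)))
  if (any(abs(cf) * spread > 15, na.rm = TRUE)) {
    abort("Separation detected: a coefficient diverged beyond 15 log-odds.",
          class = "airspace_error_separation")
  }
  new_assoc_result(fit, predictors[1], adjusted = length(predictors) > 1)
}

#' Logistic fit adjusted for a spirometry-availability propensity score
#'
#' Stage 1 models the probability of carrying spirometry on the covariates
#' (logistic); the fitted probability is each patient's propensity score.
#' Stage 2 refits the outcome model with the score added as a covariate. If
#' the availability indicator is constant (stage 1 degenerate) the
#' unadjusted fit is returned with a warning and a note.
#'
#' @param data Patient data frame.
#' @param outcome,predictors As in [logistic_fit()].
#' @param availability Name of the logical spirometry-availability column.
#' @param score_covariates Covariates for the stage-1 availability model;
#'   defaults to `predictors` without the exposure.
#' @return A `copd_assoc` with the score in `terms` when adjustment was
#'   possible.
#' @export
propensity_covariate_fit <- function(data, outcome = "copd",
                                     predictors = "group",
                                     availability = "spirometry_available",
                                     score_covariates = NULL) {
  stopifnot(is.data.frame(data))
  avail <- data[[availability]]
  if (is.null(avail)) {
    abort(sprintf("Column '%s' not found.", availability),
          class = "airspace_error_validation")
  }
  if (length(unique(avail)) < 2) {
    warn("Spirometry availability is constant; returning the unadjusted fit.")
    res <- logistic_fit(data, outcome, predictors)
    res$note <- "propensity stage degenerate; unadjusted"
    return(res)
  }
  covs <- score_covariates %||% setdiff(predictors, predictors[1])
  if (length(covs) == 0) covs <- "1"
  f1 <- stats::reformulate(covs, response = availability)
  stage1 <- suppressWarnings(glm(f1, family = binomial(), data = data))
  data$.propensity_score <- stats::fitted(stage1)
  logistic_fit(data, outcome, c(predictors, ".propensity_score"))
}
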