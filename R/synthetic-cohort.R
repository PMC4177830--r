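#' Default per-group covariate prevalences for the synthetic cohort
#'
#' Prevalences of the baseline binary covariates in each disease group of a
#' two-group vascular-surgery cohort (aortic aneurysm, AA, versus arterial
#' occlusive disease, AOD), matching the published clinical
#' characteristics of such a cohort.
#'
#' @return Named list with elements `AA` and `AOD`, each a named probability
#'   vector.
#' @export
default_covariate_prevalences <- function() {
  list(
    AA = c(gender_male = 0.855, chf = 0.107, ihd = 0.443, cvd = 0.145,
           kidney_disease = 0.153, diabetes = 0.168, hypertension = 0.664,
           hypercholesterolemia = 0.870, smoking_current = 0.384,
           smoking_ever = 0.770, statins = 0.726, beta_blockers = 0.864,
           ras_inhibitors = 0.441, diuretics = 0.224, antiplatelets = 0.574),
    AOD = c(gender_male = 0.669, chf = 0.114, ihd = 0.393, cvd = 0.470,
            kidney_disease = 0.136, diabetes = 0.289, hypertension = 0.672,
            hypercholesterolemia = 0.906, smoking_current = 0.433,
            smoking_ever = 0.787, statins = 0.813, beta_blockers = 0.759,
            ras_inhibitors = 0.473, diuretics = 0.270, antiplatelets = 0.745)
  )
}

#' Parameters for the synthetic vascular-surgery cohort
#'
#' The generator draws a two-group cohort (AA vs AOD) with the covariate
#' structure of a clinical baseline table and a COPD outcome from an
#' explicit logistic model, so that association analyses can be checked
#' against planted coefficients. The defaults reproduce the published
#' marginal conditions: group split 614/1393, COPD prevalence 26 percent in
#' AOD, group log-odds `log(2.08)` (which gives about 42 percent in AA), and
#' spirometry available for 92 percent of records. Covariate effects on
#' COPD default to zero and are configurable.
#'
#' @param n_patients Number of patients, > 0.
#' @param p_group_aa Probability of the AA group.
#' @param covariate_prevalences As [default_covariate_prevalences()].
#' @param beta0 Intercept of the COPD logistic model (log-odds in the AOD
#'   group at covariate reference).
#' @param beta_group Log-odds ratio of COPD for AA vs AOD.
#' @param beta_covariates Named log-odds coefficients for binary covariates
#'   (default: none).
#' @param p_spirometry Probability a record carries spirometry.
#' @param gold_split Probabilities of GOLD classes I, II, III/IV among COPD
#'   cases (severity split within COPD is not printed in baseline tables;
#'   this default puts half of cases in the moderate class).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 1393, p_group_aa = 614 / 1393,
                              covariate_prevalences = default_covariate_prevalences(),
                              beta0 = qlogis(0.26), beta_group = log(2.08),
                              beta_covariates = numeric(0),
                              p_spirometry = 0.92,
                              gold_split = c(I = 0.3, II = 0.5, `III/IV` = 0.2),
                              seed = 1L) {
  stop_if_not_scalar_number(n_patients, "n_patients", min = 1)
  stop_if_not_probability(p_group_aa, "p_group_aa")
  stop_if_not_probability(p_spirometry, "p_spirometry")
  for (g in names(covariate_prevalences)) {
    pv <- covariate_prevalences[[g]]
    if (any(pv < 0 | pv > 1)) {
      abort(sprintf("Prevalences for group '%s' must be probabilities.", g),
            class = "airspace_error_validation")
    }
  }
  if (!all(is.finite(c(beta0, beta_group, beta_covariates)))) {
    abort("Logistic coefficients must be finite.",
          class = "airspace_error_validation")
  }
  if (abs(sum(gold_split) - 1) > 1e-8 || any(gold_split < 0)) {
    abort("`gold_split` must be non-negative and sum to 1.",
          class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(seed, "seed")
  structure(list(n_patients = as.integer(n_patients),
                 p_group_aa = p_group_aa,
                 covariate_prevalences = covariate_prevalences,
                 beta0 = beta0, beta_group = beta_group,
                 beta_covariates = beta_covariates,
                 p_spirometry = p_spirometry, gold_split = gold_split,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Generate a synthetic two-group vascular-surgery cohort
#'
#' One row per patient. Group membership is Bernoulli(`p_group_aa`); binary
#' covariates are Bernoulli at their per-group prevalences (current smoking
#' is drawn conditionally within ever-smokers so the two flags are
#' consistent); age, BMI and hs-CRP are continuous with group-specific
#' distributions. COPD is drawn from the logistic model
#' `logit P(COPD) = beta0 + beta_group [group == AA] + sum beta_j x_j`; COPD
#' cases receive a GOLD class from `gold_split`, and spirometry values
#' (FEV1/FVC ratio, percent-predicted FEV1) are drawn inside the ranges that
#' [classify_gold()] maps back to the assigned class. Records without
#' spirometry keep their generative COPD status and carry `NA` spirometry
#' with `spirometry_available = FALSE`.
#'
#' @param params A [cohort_sim_params()] list.
#' @return A tibble with one `PatientRecord` per row.
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n <- params$n_patients
  withr::with_seed(params$seed, {
    aa <- runif(n) < params$p_group_aa
    grp <- ifelse(aa, "AA", "AOD")
    prev <- params$covariate_prevalences
    covs <- names(prev[[1]])
    df <- tibble::tibble(patient_id = seq_len(n),
                         group = factor(grp, levels = c("AOD", "AA")))
    for (v in setdiff(covs, "smoking_current")) {
      p <- ifelse(aa, prev[["AA"]][[v]], prev[["AOD"]][[v]])
      df[[v]] <- runif(n) < p
    }
    # current smokers are a subset of ever smokers
    cur_given_ever <- function(g) {
      pe <- prev[[g]][["smoking_ever"]]
      if (pe > 0) min(1, prev[[g]][["smoking_current"]] / pe) else 0
    }
    p_cur <- ifelse(aa, cur_given_ever("AA"), cur_given_ever("AOD"))
    df$smoking_current <- df$smoking_ever & (runif(n) < p_cur)
    df$age <- rnorm(n, ifelse(aa, 71.4, 65.6), ifelse(aa, 7.8, 11.0))
    df$bmi <- rnorm(n, ifelse(aa, 26.1, 26.2), ifelse(aa, 3.9, 4.3))
    df$hs_crp <- rlnorm(n, log(ifelse(aa, 5.9, 4.8)),
                        ifelse(aa, 1.084, 1.235))

    lp <- params$beta0 + params$beta_group * aa
    for (v in names(params$beta_covariates)) {
      lp <- lp + params$beta_covariates[[v]] * as.numeric(df[[v]])
    }
    df$copd <- runif(n) < plogis(lp)

    gold <- rep("none", n)
    ncopd <- sum(df$copd)
    if (ncopd > 0) {
      gold[df$copd] <- sample(names(params$gold_split), ncopd,
                              replace = TRUE, prob = params$gold_split)
    }
    df$gold <- factor(gold, levels = c("none", "I", "II", "III/IV"))
    df$spirometry_available <- runif(n) < params$p_spirometry

    # spirometry drawn inside the ranges classify_gold() maps back to the
    # assigned class
    ratio_lo <- ifelse(df$copd, 0.40, 0.701)
    ratio_hi <- ifelse(df$copd, 0.699, 0.92)
    fev1_lo <- c(none = 80, I = 80.5, II = 50, `III/IV` = 25)[as.character(df$gold)]
    fev1_hi <- c(none = 120, I = 110, II = 80, `III/IV` = 49.5)[as.character(df$gold)]
    ratio <- runif(n, ratio_lo, ratio_hi)
    fev1 <- runif(n, fev1_lo, fev1_hi)
    ratio[!df$spirometry_available] <- NA_real_
    fev1[!df$spirometry_available] <- NA_real_
    df$fev1_fvc_ratio <- ratio
    df$fev1_pct_pred <- fev1
    df
  })
}
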