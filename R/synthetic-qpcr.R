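#' Parameters for the synthetic qPCR panel
#'
#' Emulates a relative-quantification experiment: one target and one
#' housekeeping gene measured in replicate (triplicate by default) across
#' samples of several genotypes, with planted true expression ratios
#' relative to wild type. Under perfect efficiency each halving of
#' expression raises the target Ct by one cycle, so
#' `Ct = base_ct - log2(true ratio) + noise`; the housekeeping gene has
#' ratio fixed at 1. Default ratios 1 / 0.5 / 0.25 plant a 2-fold lower
#' heterozygous and 4-fold lower homozygous expression.
#'
#' @param genotype_ratios Named positive true expression ratios relative to
#'   the first (reference) genotype.
#' @param base_ct_target,base_ct_housekeeping Baseline Ct values in cycles.
#' @param ct_noise_sd Replicate noise SD in cycles (>= 0).
#' @param n_replicates Replicates per reaction, >= 1 (default 3).
#' @param n_samples Samples per genotype (default 4, a typical per-genotype
#'   animal count).
#' @param seed Integer seed.
#' @return A list of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(genotype_ratios = c(wt = 1, het = 0.5, hom = 0.25),
                            base_ct_target = 22, base_ct_housekeeping = 18,
                            ct_noise_sd = 0.15, n_replicates = 3,
                            n_samples = 4, seed = 1L) {
  if (is.null(names(genotype_ratios)) || any(genotype_ratios <= 0)) {
    abort("`genotype_ratios` must be named and positive.",
          class = "airspace_error_validation")
  }
  stop_if_not_scalar_number(base_ct_target, "base_ct_target", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(base_ct_housekeeping, "base_ct_housekeeping",
                            min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(ct_noise_sd, "ct_noise_sd", min = 0)
  stop_if_not_scalar_number(n_replicates, "n_replicates", min = 1)
  stop_if_not_scalar_number(n_samples, "n_samples", min = 1)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(genotype_ratios = genotype_ratios,
                 base_ct_target = base_ct_target,
                 base_ct_housekeeping = base_ct_housekeeping,
                 ct_noise_sd = ct_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "qpcr_sim_params")
}

#' Generate a synthetic qPCR panel
#'
#' @param params A [qpcr_sim_params()] list.
#' @return Long tibble with columns `gene` (`"target"` / `"housekeeping"`),
#'   `sample_id`, `genotype`, `replicate`, `ct`.
#' @export
generate_qpcr_panel <- function(params = qpcr_sim_params()) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  withr::with_seed(params$seed, {
    grid <- tidyr::expand_grid(
      genotype = names(params$genotype_ratios),
      sample = seq_len(params$n_samples),
      gene = c("target", "housekeeping"),
      replicate = seq_len(params$n_replicates))
    ratio <- params$genotype_ratios[grid$genotype]
    base <- ifelse(grid$gene == "target", params$base_ct_target,
                   params$base_ct_housekeeping)
    true_ct <- base - ifelse(grid$gene == "target", log2(ratio), 0)
    grid$ct <- true_ct + rnorm(nrow(grid), 0, params$ct_noise_sd)
    grid$sample_id <- paste0(grid$genotype, "_", grid$sample)
    tibble::as_tibble(grid[, c("gene", "sample_id", "genotype",
                               "replicate", "ct")])
  })
}
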