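#' Mean cycle threshold of replicate reactions
#'
#' Replicate Ct values are averaged on the cycle scale (before any
#' exponentiation), matching how triplicate reactions are pooled.
#'
#' @param ct Numeric vector of at least one finite positive Ct value.
#' @return The arithmetic mean Ct.
#' @export
mean_ct <- function(ct) {
  if (length(ct) < 1 || !is.numeric(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    abort("Need at least one finite positive Ct replicate.",
          class = "airspace_error_validation")
  }
  mean(ct)
}

#' Relative gene expression from delta-Ct values
#'
#' The housekeeping-normalised relative expression
#' \deqn{2^{(Ct_{control} - Ct_{sample})_{gene}} /
#'       2^{(Ct_{control} - Ct_{sample})_{housekeeping}}}
#' assuming perfect amplification efficiency (a factor of exactly 2 per
#' cycle). A sample whose target Ct sits one cycle above the control with
#' identical housekeeping Cts has relative expression 0.5, i.e. a 2-fold
#' lower expression.
#'
#' @param ct_gene_sample,ct_gene_control Target-gene Ct values.
#' @param ct_hk_sample,ct_hk_control Housekeeping-gene Ct values.
#' @return The expression ratio (vectorised).
#' @export
relative_expression <- function(ct_gene_sample, ct_gene_control,
                                ct_hk_sample, ct_hk_control) {
  vals <- c(ct_gene_sample, ct_gene_control, ct_hk_sample, ct_hk_control)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("All Ct values must be finite numbers.",
          class = "airspace_error_validation")
  }
  2^(ct_gene_control - ct_gene_sample) / 2^(ct_hk_control - ct_hk_sample)
}

#' Per-genotype fold changes relative to wild type
#'
#' Pools replicate Cts to per-sample means ([mean_ct()]), computes each
#' sample's relative expression against the reference-genotype mean Cts, and
#' reports per-genotype mean relative expression divided by the reference
#' mean, together with the reciprocal fold-lower value.
#'
#' @param panel Long tibble with columns `gene`, `sample_id`, `genotype`,
#'   `ct` (one row per replicate), as produced by [generate_qpcr_panel()].
#' @param reference Reference genotype (default `"wt"`).
#' @param target_gene,housekeeping_gene Gene labels in `panel`.
#' @return Tibble with `genotype`, `n_samples`, `relative_expression`,
#'   `ratio_vs_reference`, `fold_lower`.
#' @export
fold_change_by_genotype <- function(panel, reference = "wt",
                                    target_gene = "target",
                                    housekeeping_gene = "housekeeping") {
  stopifnot(is.data.frame(panel))
  need <- c("gene", "sample_id", "genotype", "ct")
  if (!all(need %in% names(panel))) {
    abort(sprintf("Panel must have columns %s.", paste(need, collapse = ", ")),
          class = "airspace_error_validation")
  }
  if (!reference %in% panel$genotype) {
    abort(sprintf("Reference genotype '%s' missing from the panel.", reference),
          class = "airspace_error_validation")
  }
  if (!all(c(target_gene, housekeeping_gene) %in% panel$gene)) {
    abort("Target or housekeeping gene missing from the panel.",
          class = "airspace_error_validation")
  }
  per_sample <- panel |>
    dplyr::group_by(.data$genotype, .data$sample_id, .data$gene) |>
    dplyr::summarise(ct = mean_ct(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  ct_gene_control <- mean(per_sample[[target_gene]][per_sample$genotype == reference])
  ct_hk_control <- mean(per_sample[[housekeeping_gene]][per_sample$genotype == reference])
  per_sample$rel_expr <- relative_expression(
    per_sample[[target_gene]], ct_gene_control,
    per_sample[[housekeeping_gene]], ct_hk_control)
  out <- per_sample |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     relative_expression = mean(.data$rel_expr),
                     .groups = "drop")
  ref_mean <- out$relative_expression[out$genotype == reference]
  out$ratio_vs_reference <- out$relative_expression / ref_mean
  out$fold_lower <- 1 / out$ratio_vs_reference
  out
}
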