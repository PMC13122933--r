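#' Benjamini-Yekutieli false-discovery-rate adjustment
#'
#' Step-up FDR control valid under arbitrary dependence between tests —
#' appropriate when conditions share genetic risk loci and outcomes are
#' correlated. With `c(m) = sum(1/i)` over the `m` tests, the raw adjusted
#' value at rank `i` is `p_(i) * m * c(m) / i`, made monotone by a
#' cumulative minimum from the largest rank down and capped at 1 (as
#' implemented by `stats::p.adjust(method = "BY")`).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param alpha rejection level on the adjusted values, default 0.05.
#' @return A tibble with `pval`, `by_adjusted_p`, `passes_fdr`, in input
#'   order.
#' @export
#' @examples
#' by_fdr(c(0.01, 0.02, 0.9))
by_fdr <- function(pvals, alpha = 0.05) {
  if (length(pvals) < 1 || any(!is.finite(pvals)) ||
      any(pvals <= 0 | pvals > 1)) {
    abort("p-values must be finite and lie in (0, 1]",
          class = "mrliability_input_error")
  }
  adjusted <- p.adjust(pvals, method = "BY")
  tibble(pval = pvals, by_adjusted_p = adjusted, passes_fdr = adjusted <= alpha)
}

#' Two-tier follow-up selection over the primary analysis grid
#'
#' Flags condition-outcome IVW results for sensitivity follow-up when either
#' (i) `p < 0.05`, or (ii) the per-doubling odds ratio exceeds 1.05 or falls
#' below 0.95 with `p < 0.10` (strict inequalities). Criterion (ii) applies
#' to binary outcomes only. Selecting on significance alone is avoided
#' because the outcomes are rare but clinically important and modest effects
#' matter; the looser second tier catches sizeable but imprecise estimates.
#' Benjamini-Yekutieli adjusted p-values over the full grid are attached so
#' multiple-testing survival can be reported alongside.
#'
#' @param results per-doubling results tibble containing exactly the primary
#'   grid's main (IVW or Wald) estimates, one row per condition-outcome
#'   pair.
#' @param alpha_i p-value threshold of criterion (i), default 0.05.
#' @param or_margin relative-effect margin of criterion (ii), default 0.05.
#' @param alpha_ii p-value threshold of criterion (ii), default 0.10.
#' @param fdr_alpha level for the FDR flags, default 0.05.
#' @param family_size size of the FDR family; defaults to `nrow(results)`.
#'   When larger (pairs missing because no instruments were available), the
#'   absent tests are treated as uninformative (p = 1) in the adjustment.
#' @return A decisions tibble sorted by condition then outcome: `condition`,
#'   `outcome`, `or_scaled`, `beta`, `pval`, `criterion_i`, `criterion_ii`,
#'   `by_adjusted_p`, `passes_fdr`, `selected`.
#' @export
select_for_followup <- function(results, alpha_i = 0.05, or_margin = 0.05,
                                alpha_ii = 0.10, fdr_alpha = 0.05,
                                family_size = NULL) {
  assert_columns(results, c("condition", "outcome", "beta", "pval", "or_scaled",
                            "scale"), "results table")
  if (!all(results$scale == "per_doubling")) {
    abort("follow-up selection expects per-doubling estimates; call scale_to_doubling() first",
          class = "mrliability_state_error")
  }
  m <- family_size %||% nrow(results)
  if (m < nrow(results)) {
    abort("family_size cannot be smaller than the number of results",
          class = "mrliability_config_error")
  }
  padded <- c(results$pval, rep(1, m - nrow(results)))
  fdr <- by_fdr(padded, alpha = fdr_alpha)[seq_len(nrow(results)), ]
  results |>
    mutate(
      criterion_i = .data$pval < alpha_i,
      criterion_ii = !is.na(.data$or_scaled) &
        (.data$or_scaled > 1 + or_margin | .data$or_scaled < 1 - or_margin) &
        .data$pval < alpha_ii,
      by_adjusted_p = fdr$by_adjusted_p,
      passes_fdr = fdr$passes_fdr,
      selected = .data$criterion_i | .data$criterion_ii
    ) |>
    select(all_of(c("condition", "outcome", "or_scaled", "beta", "pval",
                    "criterion_i", "criterion_ii", "by_adjusted_p",
                    "passes_fdr", "selected"))) |>
    arrange(.data$condition, .data$outcome)
}

#' Summarise robustness of a followed-up result across sensitivity analyses
#'
#' A followed-up estimate is tiered `"robust"` when every available
#' sensitivity estimate is directionally concordant with the main estimate
#' (same sign of the log-odds effect) and no single-SNP omission flips the
#' direction; `"uncertain"` otherwise. Analyses that could not be run are
#' counted as unevaluable, never as discordant.
#'
#' @param main_beta the main IVW log-odds estimate for the pair.
#' @param bundle tibble of sensitivity estimates with columns `analysis`
#'   (free-text label, e.g. "egger", "weighted_median", "steiger",
#'   "no_hla", "fetal_wlm", "loo_snp:<rsid>", "loo_study:<label>") and
#'   `beta` (`NA` where the analysis was unevaluable).
#' @return One-row tibble: `tier`, `n_analyses`, `n_concordant`,
#'   `n_discordant`, `n_unevaluable`.
#' @export
summarize_robustness <- function(main_beta, bundle) {
  assert_columns(bundle, c("analysis", "beta"), "sensitivity bundle")
  if (nrow(bundle) == 0) {
    abort("empty sensitivity bundle", class = "mrliability_input_error")
  }
  evaluable <- !is.na(bundle$beta)
  concordant <- evaluable & sign(bundle$beta) == sign(main_beta)
  tibble(
    tier = if (all(concordant[evaluable])) "robust" else "uncertain",
    n_analyses = nrow(bundle),
    n_concordant = sum(concordant),
    n_discordant = sum(evaluable & !concordant),
    n_unevaluable = sum(!evaluable)
  )
}
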