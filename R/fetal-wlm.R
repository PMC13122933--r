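#' Direct maternal effect from maternal and fetal marginal GWAS
#'
#' A maternal variant transmitted to the fetus can act on a pregnancy
#' outcome through the fetal genome rather than through maternal liability.
#' Under the allele-transmission model the marginal maternal association
#' `M = a + b/2` and the marginal fetal association `F = b + a/2`, where `a`
#' is the direct maternal effect and `b` the direct fetal effect. Solving
#' for `a` gives the weighted linear model adjustment
#' `a = (4M - 2F) / 3` with
#' `var(a) = (16 se_m^2 + 4 se_f^2 - 16 cov_mf) / 9`.
#'
#' @param duos tibble with one row per SNP: `rsid`, `beta_m`, `se_m`
#'   (maternal marginal), `beta_f`, `se_f` (fetal marginal), and optionally
#'   `cov_mf` (covariance between the two estimates; 0 when the samples are
#'   independent — the default).
#' @return A tibble `rsid`, `beta_adj`, `se_adj` with the direct maternal
#'   effect and its standard error.
#' @export
#' @examples
#' wlm_adjust(tibble::tibble(rsid = "rs1", beta_m = 0.3, se_m = 0.05,
#'                           beta_f = 0.15, se_f = 0.05))
wlm_adjust <- function(duos) {
  assert_columns(duos, c("rsid", "beta_m", "se_m", "beta_f", "se_f"),
                 "duo associations")
  if (!"cov_mf" %in% names(duos)) duos$cov_mf <- 0
  duos$cov_mf[is.na(duos$cov_mf)] <- 0
  if (any(duos$se_m <= 0 | duos$se_f <= 0, na.rm = TRUE)) {
    abort("duo standard errors must be > 0", class = "mrliability_input_error")
  }
  var_a <- (16 * duos$se_m^2 + 4 * duos$se_f^2 - 16 * duos$cov_mf) / 9
  if (any(var_a <= 0)) {
    abort("cov_mf too large: adjusted variance is non-positive for at least one SNP",
          class = "mrliability_input_error")
  }
  tibble(
    rsid = duos$rsid,
    beta_adj = (4 * duos$beta_m - 2 * duos$beta_f) / 3,
    se_adj = sqrt(var_a)
  )
}

#' IVW estimate on fetal-genotype-adjusted outcome associations
#'
#' Replaces each covered instrument's outcome association with the
#' WLM-adjusted direct maternal effect from [wlm_adjust()], drops
#' instruments without duo coverage (reporting the count), and reruns IVW.
#' Comparing this fit with the unadjusted one shows whether inherited fetal
#' genotype, rather than maternal liability, drives an association.
#'
#' @param pairs harmonized table.
#' @param duos duo-association tibble covering at least two of the set's
#'   instruments (see [wlm_adjust()]).
#' @return An `mr_fit` tagged with `adjustment = "fetal_wlm"`.
#' @export
mr_with_fetal_adjustment <- function(pairs, duos) {
  pairs <- check_pairs(pairs, 2, "fetal-genotype adjustment")
  adj <- wlm_adjust(duos)
  covered <- pairs$rsid %in% adj$rsid
  if (sum(covered) < 2) {
    abort(sprintf("only %d instrument(s) covered by duo associations; need at least 2",
                  sum(covered)),
          class = "mrliability_insufficient_instruments")
  }
  if (any(!covered)) {
    inform(sprintf("fetal adjustment: dropping %d instrument(s) without duo coverage",
                   sum(!covered)))
  }
  kept <- pairs[covered, ]
  idx <- match(kept$rsid, adj$rsid)
  kept$beta_out <- adj$beta_adj[idx]
  kept$se_out <- adj$se_adj[idx]
  kept$pval_out <- z_pvalue(kept$beta_out, kept$se_out)
  fit <- mr_ivw(kept)
  fit$adjustment <- "fetal_wlm"
  fit
}
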