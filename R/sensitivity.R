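#' Steiger directionality filtering
#'
#' Guards against reverse causation by removing instruments that explain
#' more variance in the outcome than in the condition. Per SNP, each side's
#' effect is converted to a correlation proxy `r = z / sqrt(z^2 + n)` with
#' `z = beta / se`; a SNP is removed iff `r2_out > r2_exp` AND the
#' two-sample comparison of Fisher-transformed correlations,
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp-3) + 1/(n_out-3))`,
#' is significant at `alpha` one-sided in the wrong direction. SNPs whose
#' sample size on either side is missing or <= 3 cannot be evaluated and are
#' retained with a flag.
#'
#' @param pairs harmonized table with per-side sample sizes (`n_exp`,
#'   `n_out`).
#' @param alpha one-sided significance level for removal, default 0.05.
#' @return A list: `retained` (the filtered harmonized table) and `records`
#'   (per-SNP audit: `rsid`, `r2_exp`, `r2_out`, `direction_ok`,
#'   `steiger_pval`, `unevaluable`, `removed`).
#' @export
steiger_filter <- function(pairs, alpha = 0.05) {
  pairs <- check_pairs(pairs, 1, "Steiger filtering")
  assert_columns(pairs, c("n_exp", "n_out"), "harmonized pairs")
  z_exp <- pairs$beta_exp / pairs$se_exp
  z_out <- pairs$beta_out / pairs$se_out
  unevaluable <- is.na(pairs$n_exp) | is.na(pairs$n_out) |
    pairs$n_exp <= 3 | pairs$n_out <= 3
  if (any(unevaluable)) {
    inform(sprintf("steiger_filter: %d SNP(s) unevaluable (missing or tiny n); retained",
                   sum(unevaluable)))
  }
  r_exp <- abs(z_exp) / sqrt(z_exp^2 + pairs$n_exp)
  r_out <- abs(z_out) / sqrt(z_out^2 + pairs$n_out)
  z_stat <- rep(NA_real_, nrow(pairs))
  ok <- !unevaluable
  z_stat[ok] <- (atanh(r_exp[ok]) - atanh(r_out[ok])) /
    sqrt(1 / (pairs$n_exp[ok] - 3) + 1 / (pairs$n_out[ok] - 3))
  steiger_pval <- pnorm(z_stat)  # one-sided: small when outcome r2 dominates
  direction_ok <- r_out^2 <= r_exp^2
  removed <- !unevaluable & !direction_ok & steiger_pval < alpha
  records <- tibble(
    rsid = pairs$rsid,
    r2_exp = r_exp^2, r2_out = r_out^2,
    direction_ok = direction_ok,
    steiger_pval = steiger_pval,
    unevaluable = unevaluable,
    removed = removed
  )
  list(retained = pairs[!removed, ], records = records)
}

#' Post-filter estimate with automatic estimator fallback
#'
#' IVW when two or more instruments remain, the Wald ratio when exactly one
#' remains, `NULL` when none do.
#'
#' @param pairs harmonized table (e.g. `steiger_filter(...)$retained`).
#' @return An `mr_fit` or `NULL`.
#' @export
mr_estimate_auto <- function(pairs) {
  retained <- if ("disposition" %in% names(pairs)) harmonized_pairs(pairs) else pairs
  if (nrow(retained) == 0) return(NULL)
  if (nrow(retained) == 1) return(mr_wald_ratio(retained))
  mr_ivw(retained)
}

#' Leave-one-SNP-out sensitivity analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn and flags
#' influential SNPs: by default, a SNP whose omission flips the sign of the
#' estimate or moves it by more than `influence_fraction` of the full-set
#' magnitude. All deltas are returned so other rules can be applied.
#'
#' @param pairs harmonized table with at least three retained instruments.
#' @param influence_fraction fraction of the full-set estimate's magnitude
#'   beyond which an omission-induced shift is flagged, default 0.5.
#' @return A tibble with one row per omitted SNP: `omitted_id`, `n_snp`,
#'   `beta`, `se`, `pval`, `delta_vs_full`, `influential`.
#' @export
leave_one_snp_out <- function(pairs, influence_fraction = 0.5) {
  pairs <- check_pairs(pairs, 3, "leave-one-SNP-out")
  full <- mr_ivw(pairs)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    fit <- mr_estimate_auto(pairs[-i, ])
    delta <- fit$beta - full$beta
    tibble(
      omitted_id = pairs$rsid[i],
      n_snp = fit$n_snp, beta = fit$beta, se = fit$se, pval = fit$pval,
      delta_vs_full = delta,
      influential = sign(fit$beta) != sign(full$beta) |
        abs(delta) > influence_fraction * abs(full$beta)
    )
  })
}

#' Fixed-effect meta-analysis of per-study outcome associations
#'
#' Per rsid, combines study-level effects by inverse-variance weighting:
#' `beta = sum(beta_s / se_s^2) / sum(1 / se_s^2)`,
#' `se = (sum(1 / se_s^2))^(-1/2)`. Studies are assumed to report effects
#' for the same effect allele.
#'
#' @param studies named list of summary-statistics tibbles, one per study.
#' @param trait_id,trait_type metadata for the pooled dataset; default taken
#'   from the first study.
#' @return A pooled summary-statistics tibble (allele and position columns
#'   from the first study covering each rsid; p-values recomputed from the
#'   pooled z-statistic).
#' @export
meta_analyze_studies <- function(studies, trait_id = NULL, trait_type = NULL) {
  stopifnot(is.list(studies), length(studies) >= 1)
  stacked <- bind_rows(studies, .id = "study")
  trait_id <- trait_id %||% studies[[1]]$trait_id[1]
  trait_type <- trait_type %||% studies[[1]]$trait_type[1]
  pooled <- stacked |>
    group_by(.data$rsid) |>
    summarise(
      chrom = dplyr::first(.data$chrom),
      pos = dplyr::first(.data$pos),
      effect_allele = dplyr::first(.data$effect_allele),
      other_allele = dplyr::first(.data$other_allele),
      eaf = dplyr::first(.data$eaf),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n = sum(.data$n),
      n_case = sum(.data$n_case),
      n_control = sum(.data$n_control),
      .groups = "drop"
    ) |>
    mutate(pval = pmax(z_pvalue(.data$beta, .data$se), .Machine$double.xmin))
  as_summary_stats(pooled, trait_id = trait_id, trait_type = trait_type)
}

#' Leave-one-study-out sensitivity analysis
#'
#' For each omitted outcome study, re-meta-analyses the remaining studies
#' (fixed-effect inverse variance), drops SNPs covered by no remaining
#' study, harmonizes against the exposure instruments and reruns IVW. The
#' full-data reference is IVW on the all-study meta-analysis.
#'
#' @param studies named list of per-study outcome summary-statistics tibbles
#'   (at least two).
#' @param exposure_instruments exposure summary statistics restricted to the
#'   instruments.
#' @param palindromic_maf_threshold passed to [harmonize()].
#' @return A tibble with one row per omitted study: `omitted_id`, `n_snp`,
#'   `beta`, `se`, `pval`, `delta_vs_full`.
#' @export
leave_one_study_out <- function(studies, exposure_instruments,
                                palindromic_maf_threshold = 0.42) {
  if (!is.list(studies) || length(studies) < 2) {
    abort("leave-one-study-out needs at least two studies",
          class = "mrliability_input_error")
  }
  if (is.null(names(studies)) || any(!nzchar(names(studies)))) {
    names(studies) <- paste0("study_", seq_along(studies))
  }
  run_ivw <- function(study_subset) {
    pooled <- meta_analyze_studies(study_subset)
    h <- harmonize(exposure_instruments, pooled,
                   palindromic_maf_threshold = palindromic_maf_threshold)
    mr_estimate_auto(h)
  }
  full <- run_ivw(studies)
  purrr::map_dfr(names(studies), function(lbl) {
    fit <- run_ivw(studies[setdiff(names(studies), lbl)])
    tibble(
      omitted_id = lbl,
      n_snp = fit$n_snp, beta = fit$beta, se = fit$se, pval = fit$pval,
      delta_vs_full = fit$beta - full$beta
    )
  })
}

#' Rerun estimation excluding HLA-region instruments
#'
#' Drops instruments inside the extended HLA window (see [flag_hla()]) and
#' re-estimates: IVW with two or more remaining SNPs, the Wald ratio with
#' one, `NULL` (with a warning) when none remain.
#'
#' @param pairs harmonized table with `chrom` and `pos`.
#' @param ... region overrides passed to [flag_hla()].
#' @return An `mr_fit` with the reduced `n_snp`, or `NULL`.
#' @export
rerun_without_hla <- function(pairs, ...) {
  pairs <- check_pairs(pairs, 1, "the HLA-excluded rerun")
  keep <- !flag_hla(pairs, ...)
  if (!any(keep)) {
    warn("all instruments fall in the HLA region; no HLA-excluded estimate")
    return(NULL)
  }
  mr_estimate_auto(pairs[keep, ])
}
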