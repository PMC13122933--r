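#' Select genome-wide-significant, LD-independent instruments
#'
#' Filters a summary-statistics table at a p-value threshold and thins the
#' survivors by greedy p-value-ranked clumping: candidates are sorted by
#' ascending p-value (ties broken by rsid, lexicographically), the best
#' remaining candidate is accepted, and every candidate on the same
#' chromosome within `clump_window_kb` of it with `r2 >= clump_r2` is
#' discarded; repeat until exhausted. With no LD matrix, clumping degrades to
#' the distance-only rule (any same-chromosome pair inside the window is
#' treated as linked) with a warning, as does any candidate pair absent from
#' the matrix.
#'
#' @param exposure summary-statistics tibble; `chrom`/`pos` are required when
#'   clumping is to do anything.
#' @param ld optional square r2 matrix with rsid dimnames
#'   (see [read_ld_matrix()]).
#' @param pval_threshold genome-wide significance threshold, default `5e-8`.
#' @param clump_r2 LD threshold above which two variants are mutually
#'   exclusive, default 0.001.
#' @param clump_window_kb clumping window in kilobases, default 10000.
#' @return The accepted instruments in genomic order, with an `hla_flag`
#'   column from [flag_hla()]. Zero candidates below the threshold yield an
#'   empty tibble with a warning, not an error (externally curated
#'   instrument lists can be supplied directly via [as_summary_stats()]).
#' @export
select_instruments <- function(exposure, ld = NULL, pval_threshold = 5e-8,
                               clump_r2 = 0.001, clump_window_kb = 10000) {
  assert_columns(exposure, summary_stats_cols, "exposure dataset")
  cand <- exposure |> filter(.data$pval < pval_threshold)
  if (nrow(cand) == 0) {
    warn("no variants below the significance threshold; returning an empty instrument set")
    out <- cand
    out$hla_flag <- logical(0)
    return(out)
  }
  if (any(is.na(cand$chrom) | is.na(cand$pos))) {
    abort("clumping requires chrom and pos on every candidate",
          class = "mrliability_input_error")
  }
  cand <- cand |> arrange(.data$pval, .data$rsid)
  if (!is.null(ld)) validate_ld_matrix(ld)

  warned <- FALSE
  r2_lookup <- function(a, b) {
    if (is.null(ld) || !(a %in% rownames(ld)) || !(b %in% rownames(ld))) {
      if (!warned && !is.null(ld)) {
        warn("candidate pair(s) missing from the LD matrix; treating them as linked (distance-only clumping)")
        warned <<- TRUE
      }
      return(1)
    }
    ld[a, b]
  }
  if (is.null(ld)) {
    warn("no LD matrix supplied; clumping is distance-only (same-chromosome neighbours within the window are discarded)")
  }

  window_bp <- clump_window_kb * 1000
  remaining <- cand
  accepted <- cand[0, ]
  while (nrow(remaining) > 0) {
    best <- remaining[1, ]
    accepted <- bind_rows(accepted, best)
    near <- remaining$chrom == best$chrom &
      abs(remaining$pos - best$pos) <= window_bp
    linked <- near & vapply(remaining$rsid, r2_lookup, numeric(1), b = best$rsid) >= clump_r2
    linked[1] <- TRUE
    remaining <- remaining[!linked, ]
  }
  accepted <- accepted |> arrange(.data$chrom, .data$pos)
  accepted$hla_flag <- flag_hla(accepted)
  accepted
}

#' Mean pseudo F-statistic of an instrument set
#'
#' Instrument strength summarised as the mean over instruments of
#' `(beta / se)^2`.
#'
#' @param instruments tibble with `beta` and `se` columns; must be non-empty
#'   with finite values.
#' @return A single number.
#' @export
#' @examples
#' mean_pseudo_f(tibble::tibble(beta = c(0.1, 0.2), se = c(0.01, 0.02)))
mean_pseudo_f <- function(instruments) {
  assert_columns(instruments, c("beta", "se"), "instrument set")
  if (nrow(instruments) == 0) {
    abort("mean pseudo F-statistic is undefined for an empty instrument set",
          class = "mrliability_input_error")
  }
  z <- instruments$beta / instruments$se
  if (any(!is.finite(z))) {
    abort("instruments must have finite beta and se", class = "mrliability_input_error")
  }
  mean(z^2)
}

#' Flag variants in the extended HLA region
#'
#' The HLA region is highly pleiotropic across immune conditions and has
#' long-range LD; sensitivity reruns exclude it. The default window is
#' chr6:28,477,797-33,448,354 on GRCh37, 1-based and inclusive at both ends.
#'
#' @param variants tibble with `chrom` and `pos` columns (or a harmonized
#'   table).
#' @param chrom,start,end region definition.
#' @return Logical vector, one element per row; `NA` chrom/pos give `FALSE`.
#' @export
flag_hla <- function(variants, chrom = "6", start = 28477797L, end = 33448354L) {
  assert_columns(variants, c("chrom", "pos"), "variant table")
  ch <- sub("^chr", "", as.character(variants$chrom), ignore.case = TRUE)
  flag <- ch == as.character(chrom) & variants$pos >= start & variants$pos <= end
  flag & !is.na(flag)
}

#' Correlation of instrument effects between two conditions
#'
#' Shared instruments are oriented so that the effect allele increases
#' liability to condition A (both betas negated where `beta` of A is
#' negative), then the Pearson correlation between the oriented effect
#' vectors is computed. Used to gauge shared genetic architecture between
#' conditions whose liabilities are analysed side by side.
#'
#' @param instruments_a condition A's instrument tibble.
#' @param effects_on_b summary statistics of the same variants for
#'   condition B; harmonize to A's alleles first if the sources differ in
#'   orientation.
#' @return One-row tibble: `condition_a`, `condition_b`, `n_shared_snps`,
#'   `pearson_r` (NA with fewer than 2 shared variants), `alignment` note.
#' @export
cross_condition_correlation <- function(instruments_a, effects_on_b) {
  assert_columns(instruments_a, c("rsid", "beta", "trait_id"), "instrument set")
  assert_columns(effects_on_b, c("rsid", "beta", "trait_id"), "condition B dataset")
  shared <- inner_join(
    instruments_a |> select("rsid", beta_a = "beta"),
    effects_on_b |> select("rsid", beta_b = "beta"),
    by = "rsid"
  )
  r <- if (nrow(shared) >= 2) {
    flip <- shared$beta_a < 0
    cor(ifelse(flip, -shared$beta_a, shared$beta_a),
        ifelse(flip, -shared$beta_b, shared$beta_b))
  } else {
    NA_real_
  }
  tibble(
    condition_a = instruments_a$trait_id[1],
    condition_b = effects_on_b$trait_id[1],
    n_shared_snps = nrow(shared),
    pearson_r = r,
    alignment = "effects oriented to condition-A risk-increasing alleles"
  )
}
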