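harmonized_cols <- c("condition_id", "outcome_id", "rsid", "chrom", "pos",
                     "effect_allele", "other_allele",
                     "beta_exp", "se_exp", "pval_exp", "eaf_exp", "n_exp",
                     "n_case_exp", "n_control_exp",
                     "beta_out", "se_out", "pval_out", "eaf_out", "n_out",
                     "n_case_out", "n_control_out",
                     "outcome_type", "disposition")

kept_dispositions <- c("kept", "flipped", "strand_corrected")

#' Align exposure instruments and outcome associations to a common effect allele
#'
#' For each instrument rsid present in the outcome dataset, aligns the
#' outcome association to the exposure's effect allele:
#'
#' * same allele pair, same orientation: kept as is (`kept`);
#' * same pair, swapped orientation: outcome beta negated and `eaf_out`
#'   replaced by `1 - eaf_out` (`flipped`);
#' * pair matches only under strand complement (A<->T, C<->G): outcome
#'   alleles complemented first (`strand_corrected`);
#' * palindromic pair (A/T or C/G), where allele labels cannot distinguish
#'   strands: orientation inferred from allele frequencies — kept when both
#'   frequencies are informative (minor-allele frequency below
#'   `palindromic_maf_threshold`) and on the same side of 0.5, sign-flipped
#'   when on opposite sides, and `dropped_palindromic` otherwise;
#' * irreconcilable allele pairs: `dropped_mismatch`.
#'
#' Instruments absent from the outcome dataset are recorded with disposition
#' `missing` (no proxy search is attempted). All removals are dispositions in
#' the returned table, never errors.
#'
#' @param exposure summary-statistics tibble restricted to the instruments.
#' @param outcome summary-statistics tibble for the outcome trait.
#' @param palindromic_maf_threshold minor-allele-frequency bound below which
#'   a palindromic variant's frequency is considered informative; in
#'   (0, 0.5), default 0.42.
#' @return A tibble with one row per instrument carrying exposure and
#'   outcome effects in the exposure's allele orientation and a
#'   `disposition` column. Use [harmonized_pairs()] to keep only usable rows
#'   and [harmonization_audit()] for the per-disposition counts.
#' @export
#' @examples
#' exp <- as_summary_stats(data.frame(
#'   rsid = "rs1", effect_allele = "A", other_allele = "G",
#'   beta = 0.1, se = 0.01, pval = 1e-10), "cond")
#' out <- as_summary_stats(data.frame(
#'   rsid = "rs1", effect_allele = "G", other_allele = "A",
#'   beta = -0.05, se = 0.02, pval = 0.01), "outc")
#' harmonize(exp, out)
harmonize <- function(exposure, outcome, palindromic_maf_threshold = 0.42) {
  assert_columns(exposure, summary_stats_cols, "exposure dataset")
  assert_columns(outcome, summary_stats_cols, "outcome dataset")
  assert_scalar_number(palindromic_maf_threshold, "palindromic_maf_threshold",
                       lower = 1e-12, upper = 0.5 - 1e-12)

  out_idx <- match(exposure$rsid, outcome$rsid)
  rows <- purrr::map(seq_len(nrow(exposure)), function(i) {
    e <- exposure[i, ]
    j <- out_idx[i]
    if (is.na(j)) {
      return(harmonized_row(e, NULL, "missing"))
    }
    o <- outcome[j, ]
    align_pair(e, o, palindromic_maf_threshold)
  })
  res <- bind_rows(rows)
  res$condition_id <- exposure$trait_id[1]
  res$outcome_id <- if (nrow(outcome) > 0) outcome$trait_id[1] else NA_character_
  res$outcome_type <- if (nrow(outcome) > 0) outcome$trait_type[1] else NA_character_
  res |> select(all_of(harmonized_cols))
}

harmonized_row <- function(e, o, disposition) {
  tibble(
    condition_id = NA_character_, outcome_id = NA_character_,
    rsid = e$rsid, chrom = e$chrom, pos = e$pos,
    effect_allele = e$effect_allele, other_allele = e$other_allele,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf_exp = e$eaf,
    n_exp = e$n, n_case_exp = e$n_case, n_control_exp = e$n_control,
    beta_out = if (is.null(o)) NA_real_ else o$beta,
    se_out = if (is.null(o)) NA_real_ else o$se,
    pval_out = if (is.null(o)) NA_real_ else o$pval,
    eaf_out = if (is.null(o)) NA_real_ else o$eaf,
    n_out = if (is.null(o)) NA_real_ else o$n,
    n_case_out = if (is.null(o)) NA_real_ else o$n_case,
    n_control_out = if (is.null(o)) NA_real_ else o$n_control,
    outcome_type = NA_character_,
    disposition = disposition
  )
}

flip_outcome <- function(o) {
  o$beta <- -o$beta
  o$eaf <- 1 - o$eaf
  tmp <- o$effect_allele
  o$effect_allele <- o$other_allele
  o$other_allele <- tmp
  o
}

align_pair <- function(e, o, thr) {
  if (is_palindromic_pair(e$effect_allele, e$other_allele)) {
    # outcome must carry the same (strand-ambiguous) pair at all
    pair_ok <- setequal(c(o$effect_allele, o$other_allele),
                        c(e$effect_allele, e$other_allele)) ||
      setequal(dna_complement(c(o$effect_allele, o$other_allele)),
               c(e$effect_allele, e$other_allele))
    if (!pair_ok) return(harmonized_row(e, o, "dropped_mismatch"))
    informative <- function(f) !is.na(f) && pmin(f, 1 - f) < thr
    if (informative(e$eaf) && informative(o$eaf)) {
      same_side <- (e$eaf - 0.5) * (o$eaf - 0.5) > 0
      if (same_side) {
        o$effect_allele <- e$effect_allele
        o$other_allele <- e$other_allele
        return(harmonized_row(e, o, "kept"))
      }
      o <- flip_outcome(o)
      o$effect_allele <- e$effect_allele
      o$other_allele <- e$other_allele
      return(harmonized_row(e, o, "flipped"))
    }
    return(harmonized_row(e, o, "dropped_palindromic"))
  }

  same <- o$effect_allele == e$effect_allele && o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele && o$other_allele == e$effect_allele
  if (same) return(harmonized_row(e, o, "kept"))
  if (swapped) return(harmonized_row(e, flip_outcome(o), "flipped"))

  oc <- o
  oc$effect_allele <- dna_complement(o$effect_allele)
  oc$other_allele <- dna_complement(o$other_allele)
  same_c <- oc$effect_allele == e$effect_allele && oc$other_allele == e$other_allele
  swapped_c <- oc$effect_allele == e$other_allele && oc$other_allele == e$effect_allele
  if (same_c) return(harmonized_row(e, oc, "strand_corrected"))
  if (swapped_c) return(harmonized_row(e, flip_outcome(oc), "strand_corrected"))
  harmonized_row(e, o, "dropped_mismatch")
}

#' Retained pairs and disposition audit of a harmonized table
#'
#' @param harmonized tibble from [harmonize()] or [read_harmonized_table()].
#' @return `harmonized_pairs()`: the rows with disposition `kept`, `flipped`
#'   or `strand_corrected`. `harmonization_audit()`: a tibble of counts per
#'   disposition.
#' @export
harmonized_pairs <- function(harmonized) {
  assert_columns(harmonized, "disposition", "harmonized table")
  harmonized |> filter(.data$disposition %in% kept_dispositions)
}

#' @rdname harmonized_pairs
#' @export
harmonization_audit <- function(harmonized) {
  harmonized |> count(.data$disposition, name = "n_snp")
}

#' Load a pre-harmonized SNP-exposure/SNP-outcome table
#'
#' Entry point for reproducing results from a published harmonized dataset:
#' a delimited table with one row per condition-outcome-SNP carrying both
#' the exposure and the outcome association already aligned to a shared
#' effect allele. All rows are taken at face value (disposition `kept`);
#' [harmonize()] is bypassed.
#'
#' Required columns: `condition`, `outcome`, `rsid`, `effect_allele`,
#' `other_allele`, `beta_exp`, `se_exp`, `beta_out`, `se_out`. Recognised
#' optional columns: `chrom`, `pos`, `pval_exp`, `pval_out`, `eaf_exp`,
#' `eaf_out`, `n_exp`, `n_out`, `n_case_exp`, `n_control_exp`, `n_case_out`,
#' `n_control_out`, `outcome_type`.
#'
#' @param path file path to a TSV (or CSV, by extension).
#' @return A harmonized tibble covering every condition-outcome pair in the
#'   file; split it per analysis with `dplyr::group_split(condition_id,
#'   outcome_id)`.
#' @export
read_harmonized_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("harmonized table not found: %s", path),
          class = "mrliability_input_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  assert_columns(raw, c("condition", "outcome", "rsid", "effect_allele",
                        "other_allele", "beta_exp", "se_exp", "beta_out", "se_out"),
                 "harmonized table")
  opt <- c("chrom", "pos", "pval_exp", "pval_out", "eaf_exp", "eaf_out",
           "n_exp", "n_out", "n_case_exp", "n_control_exp", "n_case_out",
           "n_control_out")
  for (col in setdiff(opt, names(raw))) raw[[col]] <- NA
  if (!"outcome_type" %in% names(raw)) raw$outcome_type <- "binary"
  raw |>
    mutate(
      condition_id = as.character(.data$condition),
      outcome_id = as.character(.data$outcome),
      rsid = as.character(.data$rsid),
      chrom = as.character(.data$chrom),
      pos = as.integer(.data$pos),
      effect_allele = toupper(.data$effect_allele),
      other_allele = toupper(.data$other_allele),
      across(all_of(c("beta_exp", "se_exp", "pval_exp", "eaf_exp", "n_exp",
                      "n_case_exp", "n_control_exp", "beta_out", "se_out",
                      "pval_out", "eaf_out", "n_out", "n_case_out",
                      "n_control_out")), as.numeric),
      disposition = "kept"
    ) |>
    select(all_of(harmonized_cols))
}
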