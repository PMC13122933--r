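#' Default column map for GWAS-SSF-style summary statistics
#'
#' Maps the package's standard field names to the column names used in
#' GWAS-SSF formatted files. Override individual entries to read files from
#' other sources, e.g. `ssf_column_map(rsid = "SNP", pval = "P")`.
#'
#' @param ... named overrides, `standard_field = "file_column"`.
#' @return A named character vector mapping standard field names to file
#'   column names.
#' @export
#' @examples
#' ssf_column_map()
#' ssf_column_map(rsid = "SNP", beta = "b")
ssf_column_map <- function(...) {
  map <- c(
    rsid          = "rsid",
    chrom         = "chromosome",
    pos           = "base_pair_location",
    effect_allele = "effect_allele",
    other_allele  = "other_allele",
    eaf           = "effect_allele_frequency",
    beta          = "beta",
    se            = "standard_error",
    pval          = "p_value",
    n             = "n",
    n_case        = "n_cases",
    n_control     = "n_controls"
  )
  overrides <- c(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad) > 0) {
      abort(sprintf("unknown summary-statistic field(s): %s",
                    paste(bad, collapse = ", ")),
            class = "mrliability_config_error")
    }
    map[names(overrides)] <- overrides
  }
  map
}

summary_stats_cols <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                        "eaf", "beta", "se", "pval", "n", "n_case", "n_control",
                        "trait_id", "trait_type")

#' Coerce and validate a tibble of GWAS summary statistics
#'
#' Standardises a data frame of per-variant associations into the column
#' contract used throughout the package: one row per variant with `rsid`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n`, `n_case`, `n_control`, `trait_id`, `trait_type`. Alleles are
#' upper-cased; absent optional columns are filled with `NA`.
#'
#' Validated invariants: `se > 0`, `pval` in (0, 1], `eaf` in \[0, 1\] when
#' present, `pos >= 1` when present, `effect_allele != other_allele`, unique
#' `rsid`, and `n_case + n_control == n` for binary traits when all three are
#' present.
#'
#' @param x data frame with at least `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`.
#' @param trait_id character label for the trait.
#' @param trait_type `"binary"` (effects on the log-odds scale) or
#'   `"continuous"` (SD units).
#' @return A tibble satisfying the summary-statistics column contract.
#' @export
#' @examples
#' as_summary_stats(
#'   data.frame(rsid = "rs1", effect_allele = "a", other_allele = "g",
#'              beta = 0.1, se = 0.02, pval = 1e-9),
#'   trait_id = "condition", trait_type = "binary")
as_summary_stats <- function(x, trait_id, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  assert_columns(x, c("rsid", "effect_allele", "other_allele", "beta", "se", "pval"),
                 "summary statistics")
  x <- as_tibble(x)
  for (col in setdiff(summary_stats_cols, names(x))) {
    x[[col]] <- NA
  }
  x <- x |>
    mutate(
      rsid = as.character(.data$rsid),
      chrom = as.character(.data$chrom),
      pos = as.integer(.data$pos),
      effect_allele = toupper(as.character(.data$effect_allele)),
      other_allele = toupper(as.character(.data$other_allele)),
      eaf = as.numeric(.data$eaf),
      beta = as.numeric(.data$beta),
      se = as.numeric(.data$se),
      pval = as.numeric(.data$pval),
      n = as.numeric(.data$n),
      n_case = as.numeric(.data$n_case),
      n_control = as.numeric(.data$n_control),
      trait_id = .env$trait_id,
      trait_type = .env$trait_type
    ) |>
    select(all_of(summary_stats_cols))

  if (anyDuplicated(x$rsid)) {
    abort("duplicate rsid in summary statistics; use `duplicates = \"keep_lowest_p\"` at read time",
          class = "mrliability_input_error")
  }
  if (any(x$se <= 0, na.rm = TRUE)) {
    abort("all standard errors must be > 0", class = "mrliability_input_error")
  }
  if (any(x$pval <= 0 | x$pval > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1]", class = "mrliability_input_error")
  }
  if (any(x$eaf < 0 | x$eaf > 1, na.rm = TRUE)) {
    abort("effect-allele frequencies must lie in [0, 1]", class = "mrliability_input_error")
  }
  if (any(x$pos < 1, na.rm = TRUE)) {
    abort("positions must be >= 1 (1-based)", class = "mrliability_input_error")
  }
  if (any(x$effect_allele == x$other_allele)) {
    abort("effect and other allele must differ", class = "mrliability_input_error")
  }
  if (trait_type == "binary") {
    full <- !is.na(x$n) & !is.na(x$n_case) & !is.na(x$n_control)
    if (any(full & abs(x$n_case + x$n_control - x$n) > 0.5)) {
      abort("n_case + n_control must equal n for binary traits",
            class = "mrliability_input_error")
    }
  }
  x
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited table of per-variant associations
#' (delimiter auto-detected from the file extension, `.csv` meaning comma),
#' renames columns through `column_map`, drops rows whose `beta`, `se` or
#' `pval` cannot be parsed (reporting the count), and validates the result
#' via [as_summary_stats()].
#'
#' @param path file path.
#' @param trait_id,trait_type trait metadata, see [as_summary_stats()].
#' @param column_map named character vector from [ssf_column_map()]; must
#'   cover at least rsid, effect_allele, other_allele, beta, se, pval.
#' @param delim optional explicit delimiter overriding auto-detection.
#' @param duplicates `"error"` (default) or `"keep_lowest_p"`, which keeps
#'   the record with the smallest p-value per rsid.
#' @return A summary-statistics tibble.
#' @export
read_summary_stats <- function(path, trait_id,
                               trait_type = c("binary", "continuous"),
                               column_map = ssf_column_map(),
                               delim = NULL,
                               duplicates = c("error", "keep_lowest_p")) {
  trait_type <- match.arg(trait_type)
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) {
    abort(sprintf("summary-statistics file not found: %s", path),
          class = "mrliability_input_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) {
    abort(sprintf("summary-statistics file is empty: %s", path),
          class = "mrliability_input_error")
  }
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_fields <- required[!required %in% names(column_map)]
  if (length(missing_fields) > 0) {
    abort(sprintf("column_map must cover: %s", paste(missing_fields, collapse = ", ")),
          class = "mrliability_config_error")
  }
  present <- column_map[column_map %in% names(raw)]
  absent <- setdiff(column_map[required], names(raw))
  if (length(absent) > 0) {
    abort(sprintf("mapped column(s) absent from %s: %s", path,
                  paste(absent, collapse = ", ")),
          class = "mrliability_config_error")
  }
  out <- raw[, unname(present)]
  names(out) <- names(present)

  suppressWarnings({
    for (col in intersect(c("eaf", "beta", "se", "pval", "n", "n_case", "n_control", "pos"),
                          names(out))) {
      out[[col]] <- as.numeric(out[[col]])
    }
  })
  parseable <- !is.na(out$beta) & !is.na(out$se) & !is.na(out$pval)
  n_dropped <- sum(!parseable)
  if (n_dropped > 0) {
    inform(sprintf("read_summary_stats: dropped %d row(s) with unparseable beta/se/pval",
                   n_dropped))
    out <- out[parseable, ]
  }
  if (nrow(out) == 0) {
    abort(sprintf("no usable rows in %s", path), class = "mrliability_input_error")
  }
  if (anyDuplicated(out$rsid)) {
    if (duplicates == "error") {
      abort(sprintf("duplicated rsid(s) in %s; set duplicates = \"keep_lowest_p\"", path),
            class = "mrliability_input_error")
    }
    out <- out |>
      group_by(.data$rsid) |>
      arrange(.data$pval, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup()
  }
  res <- as_summary_stats(out, trait_id = trait_id, trait_type = trait_type)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Read a square LD matrix of squared correlations
#'
#' Expects a TSV with rsids as the header row and as the first column, and
#' squared correlations (r2) in the body. Validates symmetry, unit diagonal
#' and range.
#'
#' @param path file path.
#' @return A square numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  rsids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rsids
  if (!identical(colnames(m), rsids)) {
    abort("LD matrix header rsids do not match first-column rsids",
          class = "mrliability_input_error")
  }
  validate_ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param m square numeric matrix of r2 values with rsid dimnames.
#' @export
validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("LD matrix must be square", class = "mrliability_input_error")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    abort("LD matrix must be symmetric", class = "mrliability_input_error")
  }
  if (any(abs(diag(m) - 1) > 1e-8)) {
    abort("LD matrix diagonal must be exactly 1", class = "mrliability_input_error")
  }
  if (any(m < 0 | m > 1)) {
    abort("LD r2 values must lie in [0, 1]", class = "mrliability_input_error")
  }
  m
}

results_table_cols <- c("condition", "outcome", "method", "n_snp", "beta", "se",
                        "ci_low", "ci_high", "pval", "or_scaled", "or_ci_low",
                        "or_ci_high", "q", "q_df", "q_pval", "intercept",
                        "intercept_se", "intercept_pval", "scale")

#' Write and read the fixed-layout MR results table
#'
#' `write_results_table()` writes a results tibble (as produced by
#' [mr_estimate()] or [mr_run_grid()]) to TSV with a fixed column order;
#' numeric values survive a write/read round-trip to at least 10 significant
#' digits. `read_results_table()` reads it back.
#'
#' @param results results tibble; must be non-empty.
#' @param path file path.
#' @return `write_results_table()` returns `path` invisibly;
#'   `read_results_table()` returns the results tibble.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("cannot write an empty results table", class = "mrliability_input_error")
  }
  assert_columns(results, results_table_cols, "results table")
  out <- results |> select(all_of(results_table_cols))
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, formatC(v, digits = 12, format = "g"))
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    condition = "c", outcome = "c", method = "c", scale = "c",
    .default = "d"), progress = FALSE)
  assert_columns(out, results_table_cols, "results table")
  out
}
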