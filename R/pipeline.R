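#' Run the full condition-by-outcome analysis grid
#'
#' Orchestrates the whole study graph for every condition-outcome pair:
#' instrument selection (unless pre-selected instruments are supplied),
#' harmonization, the main IVW estimate rescaled per doubling of liability,
#' MR-Egger and weighted-median comparators, Steiger filtering, the
#' HLA-excluded rerun, leave-one-SNP-out, and — when duo associations or
#' per-study outcome datasets are supplied — the fetal-genotype-adjusted
#' estimate and leave-one-study-out. The main per-doubling estimates are
#' then triaged with the two-tier follow-up rule and Benjamini-Yekutieli
#' FDR, and each selected pair gets a directional-concordance robustness
#' tier.
#'
#' Pairs that fail a precondition (no shared instruments, say) are skipped
#' and reported in the manifest; a partial grid never aborts the run.
#'
#' @param exposures named list of exposure summary-statistics tibbles (or
#'   pre-selected instrument tibbles when `select = FALSE`).
#' @param outcomes named list of outcome summary-statistics tibbles.
#' @param select run [select_instruments()] on each exposure (default
#'   `TRUE`); supply curated instrument lists and `select = FALSE` to bypass.
#' @param ld optional LD matrix for clumping.
#' @param duos optional duo-association tibble for the fetal adjustment
#'   (applied to every outcome it covers).
#' @param studies optional named list of per-study outcome dataset lists,
#'   keyed by outcome name, for leave-one-study-out.
#' @param methods estimator set for [mr_estimate()].
#' @param palindromic_maf_threshold passed to [harmonize()].
#' @param alpha_i,or_margin,alpha_ii,fdr_alpha,family_size triage
#'   parameters, see [select_for_followup()].
#' @param seed integer seed (weighted-median bootstrap).
#' @param out_dir optional directory; when given, writes `results.tsv`,
#'   `decisions.tsv`, `robustness.tsv`, `sensitivity/*.tsv` and
#'   `manifest.json`.
#' @return A list: `results` (fixed-layout results table over all pairs and
#'   methods), `decisions`, `robustness`, `sensitivity` (list of audit
#'   tables), and `manifest`.
#' @export
mr_run_grid <- function(exposures, outcomes, select = TRUE, ld = NULL,
                        duos = NULL, studies = NULL,
                        methods = c("ivw", "egger", "weighted_median"),
                        palindromic_maf_threshold = 0.42,
                        alpha_i = 0.05, or_margin = 0.05, alpha_ii = 0.10,
                        fdr_alpha = 0.05, family_size = NULL,
                        seed = 1L, out_dir = NULL) {
  stopifnot(is.list(exposures), is.list(outcomes),
            length(exposures) >= 1, length(outcomes) >= 1)
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    abort("exposures and outcomes must be named lists",
          class = "mrliability_config_error")
  }

  instruments <- purrr::map(exposures, function(ex) {
    if (select) suppressWarnings(select_instruments(ex, ld = ld)) else ex
  })

  results <- list()
  main_fits <- list()
  steiger_audit <- list()
  loo_snp_tables <- list()
  no_hla_rows <- list()
  fetal_rows <- list()
  loo_study_tables <- list()
  skips <- list()
  dispositions <- list()

  for (cond in names(instruments)) {
    for (outc in names(outcomes)) {
      key <- paste(cond, outc, sep = " -> ")
      inst <- instruments[[cond]]
      if (nrow(inst) == 0) {
        skips[[key]] <- "no instruments below the significance threshold"
        next
      }
      h <- harmonize(inst, outcomes[[outc]],
                     palindromic_maf_threshold = palindromic_maf_threshold)
      # label analyses by the grid names so every downstream table joins on them
      h$condition_id <- cond
      h$outcome_id <- outc
      dispositions[[key]] <- harmonization_audit(h)
      pairs <- harmonized_pairs(h)
      if (nrow(pairs) == 0) {
        skips[[key]] <- "no instruments available in the outcome dataset after harmonization"
        next
      }

      res <- mr_estimate(pairs, methods = methods, scale = "per_doubling",
                         seed = seed)
      main <- res |> filter(.data$method %in% c("ivw_re", "wald"))
      main_fits[[key]] <- main
      results[[key]] <- res

      sf <- steiger_filter(pairs)
      steiger_audit[[key]] <- sf$records |>
        mutate(condition = cond, outcome = outc, .before = 1)
      steiger_fit <- mr_estimate_auto(sf$retained)
      if (!is.null(steiger_fit)) {
        steiger_fit <- scale_to_doubling(steiger_fit)
        steiger_fit$method <- paste0(steiger_fit$method, "_steiger")
        results[[paste0(key, ":steiger")]] <- mr_results_table(steiger_fit)
      }

      hla_fit <- if (all(!is.na(pairs$chrom) & !is.na(pairs$pos))) {
        suppressWarnings(rerun_without_hla(pairs))
      } else {
        NULL
      }
      if (!is.null(hla_fit)) {
        hla_fit <- scale_to_doubling(hla_fit)
        hla_fit$method <- paste0(hla_fit$method, "_no_hla")
        no_hla_rows[[key]] <- mr_results_table(hla_fit)
      }

      if (nrow(pairs) >= 3) {
        loo_snp_tables[[key]] <- leave_one_snp_out(pairs) |>
          mutate(condition = cond, outcome = outc, .before = 1)
      }

      if (!is.null(duos)) {
        fit <- tryCatch(mr_with_fetal_adjustment(pairs, duos),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          fit <- scale_to_doubling(fit)
          fit$method <- "ivw_fetal_wlm"
          fetal_rows[[key]] <- mr_results_table(fit)
        }
      }

      if (!is.null(studies) && outc %in% names(studies)) {
        loo_study_tables[[key]] <- tryCatch(
          leave_one_study_out(studies[[outc]], inst,
                              palindromic_maf_threshold = palindromic_maf_threshold) |>
            mutate(condition = cond, outcome = outc, .before = 1),
          error = function(e) NULL)
      }
    }
  }

  if (length(main_fits) == 0) {
    abort("every condition-outcome pair was skipped; nothing to triage",
          class = "mrliability_input_error")
  }
  main_table <- bind_rows(main_fits)
  decisions <- select_for_followup(main_table, alpha_i = alpha_i,
                                   or_margin = or_margin, alpha_ii = alpha_ii,
                                   fdr_alpha = fdr_alpha,
                                   family_size = family_size)

  all_results <- bind_rows(c(results, no_hla_rows, fetal_rows))

  robustness <- decisions |>
    filter(.data$selected) |>
    purrr::pmap_dfr(function(condition, outcome, beta, ...) {
      key <- paste(condition, outcome, sep = " -> ")
      bundle <- bind_rows(
        all_results |>
          filter(.data$condition == !!condition, .data$outcome == !!outcome,
                 !.data$method %in% c("ivw_re", "wald")) |>
          mutate(analysis = .data$method) |>
          select("analysis", "beta"),
        (loo_snp_tables[[key]] %||% tibble(omitted_id = character(), beta = numeric())) |>
          mutate(analysis = paste0("loo_snp:", .data$omitted_id)) |>
          select("analysis", "beta"),
        (loo_study_tables[[key]] %||% tibble(omitted_id = character(), beta = numeric())) |>
          mutate(analysis = paste0("loo_study:", .data$omitted_id)) |>
          select("analysis", "beta")
      )
      if (nrow(bundle) == 0) {
        bundle <- tibble(analysis = "none_available", beta = NA_real_)
      }
      summarize_robustness(beta, bundle) |>
        mutate(condition = condition, outcome = outcome, .before = 1)
    })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrliability")),
    seed = as.integer(seed),
    config_hash = rlang::hash(list(names(exposures), names(outcomes), methods,
                                   palindromic_maf_threshold, alpha_i,
                                   or_margin, alpha_ii, fdr_alpha, family_size,
                                   seed)),
    n_pairs_run = length(main_fits),
    n_pairs_skipped = length(skips),
    skips = skips,
    dispositions = purrr::map(dispositions,
                              ~ as.list(setNames(.x$n_snp, .x$disposition))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  out <- list(
    results = all_results,
    decisions = decisions,
    robustness = robustness,
    sensitivity = list(
      steiger = bind_rows(steiger_audit),
      loo_snp = bind_rows(loo_snp_tables),
      loo_study = bind_rows(loo_study_tables)
    ),
    manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "sensitivity"), recursive = TRUE,
               showWarnings = FALSE)
    write_results_table(out$results, file.path(out_dir, "results.tsv"))
    readr::write_tsv(out$decisions, file.path(out_dir, "decisions.tsv"),
                     progress = FALSE)
    if (nrow(out$robustness) > 0) {
      readr::write_tsv(out$robustness, file.path(out_dir, "robustness.tsv"),
                       progress = FALSE)
    }
    for (nm in names(out$sensitivity)) {
      tab <- out$sensitivity[[nm]]
      if (!is.null(tab) && nrow(tab) > 0) {
        readr::write_tsv(tab, file.path(out_dir, "sensitivity",
                                        paste0(nm, ".tsv")), progress = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
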