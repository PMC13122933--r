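#' Configuration for the synthetic summary-statistics generator
#'
#' Parameterises [simulate_pair()] and friends. Effects are generated
#' directly at the summary-statistic level — the estimators only ever see
#' summary statistics, so no individual-level genotypes are needed and the
#' full recovery grids stay cheap. Defaults describe a well-powered
#' liability GWAS of a binary condition (a quarter-million participants,
#' 10% cases) against a large binary pregnancy-outcome GWAS (half a
#' million, 5% cases), with valid instruments and no allele corruption;
#' individual studies switch on pleiotropy, corruption, fetal effects or
#' study splits explicitly.
#'
#' @param k number of instruments (>= 1).
#' @param theta true causal effect: outcome log-odds per unit exposure
#'   log-odds.
#' @param maf_range interval within (0, 0.5) for minor-allele frequencies.
#' @param exposure_effect_sd SD of true instrument effects on exposure
#'   liability (log-odds per allele).
#' @param n_exp,n_out per-side GWAS sample sizes.
#' @param case_fraction_exp,case_fraction_out case fractions of the binary
#'   GWAS, entering the per-variant precision through the binomial variance
#'   factor `phi (1 - phi)`.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of direct (horizontal)
#'   pleiotropic effects on the outcome; a non-zero mean makes the
#'   pleiotropy unbalanced, which the Egger intercept should recover.
#' @param invalid_fraction share of instruments receiving pleiotropy
#'   (InSIDE holds: pleiotropy is drawn independently of instrument
#'   strength).
#' @param fetal_direct_sd SD of true direct fetal effects for
#'   [simulate_duos()].
#' @param n_studies number of outcome studies for [split_studies()].
#' @param corruption list with rates in \[0, 1\]: `allele_swap` (outcome
#'   rows reported for the other allele: alleles swapped, beta negated, eaf
#'   complemented), `strand_flip` (outcome alleles reported on the opposite
#'   strand), `palindromic` (variants assigned strand-ambiguous A/T or C/G
#'   allele pairs). [harmonize()] must repair the first two and adjudicate
#'   the third.
#' @param seed integer seed (required; same seed, same datasets).
#' @return A `sim_config` list.
#' @export
sim_config <- function(k = 100, theta = 0, maf_range = c(0.05, 0.45),
                       exposure_effect_sd = 0.08,
                       n_exp = 250000, case_fraction_exp = 0.1,
                       n_out = 500000, case_fraction_out = 0.05,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       invalid_fraction = 0, fetal_direct_sd = 0,
                       n_studies = 1,
                       corruption = list(allele_swap = 0, strand_flip = 0,
                                         palindromic = 0),
                       seed) {
  if (missing(seed)) {
    abort("`seed` is required", class = "mrliability_config_error")
  }
  assert_scalar_number(k, "k", lower = 1)
  assert_scalar_number(theta, "theta")
  assert_scalar_number(exposure_effect_sd, "exposure_effect_sd", lower = 1e-12)
  assert_scalar_number(invalid_fraction, "invalid_fraction", lower = 0, upper = 1)
  assert_scalar_number(fetal_direct_sd, "fetal_direct_sd", lower = 0)
  assert_scalar_number(n_studies, "n_studies", lower = 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5)",
          class = "mrliability_config_error")
  }
  corruption <- utils::modifyList(list(allele_swap = 0, strand_flip = 0,
                                       palindromic = 0), corruption)
  for (nm in names(corruption)) {
    assert_scalar_number(corruption[[nm]], paste0("corruption$", nm),
                         lower = 0, upper = 1)
  }
  structure(list(
    k = as.integer(k), theta = theta, maf_range = maf_range,
    exposure_effect_sd = exposure_effect_sd,
    n_exp = n_exp, case_fraction_exp = case_fraction_exp,
    n_out = n_out, case_fraction_out = case_fraction_out,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    invalid_fraction = invalid_fraction, fetal_direct_sd = fetal_direct_sd,
    n_studies = as.integer(n_studies), corruption = corruption,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# per-variant GWAS standard error for a binary trait on the log-odds scale
gwas_se <- function(maf, n, case_fraction) {
  1 / sqrt(2 * maf * (1 - maf) * n * case_fraction * (1 - case_fraction))
}

# genome-wide significance in z units: qnorm(5e-8 / 2) ~ -5.45
GWS_Z <- 5.45

#' Simulate a matched exposure/outcome summary-statistics pair
#'
#' Generates `k` independent instruments: minor-allele frequencies uniform
#' on `maf_range`; true exposure effects normal with SD
#' `exposure_effect_sd`, rejection-sampled until `|gamma| / se > 5.45` so
#' every instrument is genome-wide significant at the configured sample
#' size (the selected-instrument idealisation — winner's curse is not
#' modelled); observed exposure effects drawn about the truth with GWAS
#' precision `se = 1 / sqrt(2 maf (1-maf) n phi (1-phi))`. True outcome
#' effects are `theta * gamma + alpha`, where `alpha` is zero for valid
#' instruments and normal `(pleiotropy_mean, pleiotropy_sd)` for the
#' configured invalid fraction, drawn independently of `gamma` (InSIDE).
#' Alleles are assigned (non-palindromic unless the palindromic corruption
#' rate requests otherwise) and the outcome dataset is then corrupted at
#' the configured rates so that [harmonize()] has real work to do.
#'
#' @param config a [sim_config()].
#' @return A list: `exposure` and `outcome` summary-statistics tibbles and
#'   `truth` (per-SNP `gamma`, `alpha`, maternal direct outcome effect,
#'   `maf`, plus `theta`).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    k <- config$k
    maf <- runif(k, config$maf_range[1], config$maf_range[2])
    se_g <- gwas_se(maf, config$n_exp, config$case_fraction_exp)

    gamma <- numeric(k)
    pending <- rep(TRUE, k)
    batch <- 1000L
    proposals <- 0L
    while (any(pending)) {
      idx <- which(pending)
      draws <- matrix(rnorm(length(idx) * batch, 0, config$exposure_effect_sd),
                      nrow = length(idx))
      ok <- abs(draws) / se_g[idx] > GWS_Z
      has_hit <- rowSums(ok) > 0
      if (any(has_hit)) {
        first_hit <- apply(ok[has_hit, , drop = FALSE], 1, which.max)
        rows <- idx[has_hit]
        gamma[rows] <- draws[cbind(which(has_hit), first_hit)]
        pending[rows] <- FALSE
      }
      proposals <- proposals + batch
      if (proposals > 1e6 && any(pending)) {
        abort("could not draw genome-wide-significant instrument effects within 1e6 proposals per SNP; increase n_exp or exposure_effect_sd",
              class = "mrliability_config_error")
      }
    }

    # the effect allele is defined as the liability-increasing allele, as in
    # curated instrument lists; magnitudes keep the conditioned distribution
    gamma <- abs(gamma)

    beta_exp <- rnorm(k, gamma, se_g)
    n_invalid <- round(k * config$invalid_fraction)
    invalid <- seq_len(k) <= n_invalid  # deterministic block; gamma is iid anyway
    alpha <- ifelse(invalid,
                    rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd), 0)
    true_out <- config$theta * gamma + alpha
    se_o <- gwas_se(maf, config$n_out, config$case_fraction_out)
    beta_out <- rnorm(k, true_out, se_o)

    rsid <- sprintf("rs%07d", seq_len(k))
    chrom <- as.character(rep_len(c(1:5, 7:22), k))  # chr6 avoided: HLA-free by default
    # successive same-chromosome variants sit 30 Mb apart, well outside any
    # realistic clumping window
    pos <- as.integer(1e6 + 3e7 * ((seq_len(k) - 1) %/% 21) + seq_len(k))

    # default pair A/G (strand-unambiguous); palindromic corruption assigns
    # A/T or C/G pairs whose orientation only frequencies can resolve
    pal <- runif(k) < config$corruption$palindromic
    pal_cg <- sample(c(TRUE, FALSE), k, replace = TRUE)
    ea <- ifelse(pal & pal_cg, "C", "A")
    oa <- ifelse(pal, ifelse(pal_cg, "G", "T"), "G")
    exposure <- as_summary_stats(tibble(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_exp, se = se_g,
      pval = pmax(z_pvalue(beta_exp, se_g), .Machine$double.xmin),
      n = config$n_exp,
      n_case = round(config$n_exp * config$case_fraction_exp),
      n_control = config$n_exp - round(config$n_exp * config$case_fraction_exp)
    ), trait_id = "sim_condition", trait_type = "binary")

    outcome <- as_summary_stats(tibble(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_out, se = se_o,
      pval = pmax(z_pvalue(beta_out, se_o), .Machine$double.xmin),
      n = config$n_out,
      n_case = round(config$n_out * config$case_fraction_out),
      n_control = config$n_out - round(config$n_out * config$case_fraction_out)
    ), trait_id = "sim_outcome", trait_type = "binary")

    swap <- runif(k) < config$corruption$allele_swap
    if (any(swap)) {
      tmp <- outcome$effect_allele[swap]
      outcome$effect_allele[swap] <- outcome$other_allele[swap]
      outcome$other_allele[swap] <- tmp
      outcome$beta[swap] <- -outcome$beta[swap]
      outcome$eaf[swap] <- 1 - outcome$eaf[swap]
    }
    flip <- runif(k) < config$corruption$strand_flip
    if (any(flip)) {
      outcome$effect_allele[flip] <- dna_complement(outcome$effect_allele[flip])
      outcome$other_allele[flip] <- dna_complement(outcome$other_allele[flip])
    }

    truth <- tibble(
      rsid = rsid, maf = maf, gamma = gamma, alpha = alpha,
      maternal_direct = true_out, theta = config$theta,
      invalid = invalid, corrupted_swap = swap, corrupted_strand = flip,
      palindromic = pal
    )
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate maternal/fetal duo associations for the WLM adjustment
#'
#' Per SNP, draws a direct fetal effect `b ~ Normal(0, fetal_direct_sd^2)`,
#' forms the marginal expectations `M = a + b/2` and `F = b + a/2` from the
#' true direct maternal outcome effect `a` in `truth`, and adds GWAS noise
#' at the outcome dataset's precision. The estimate covariance is zero
#' (independent maternal and fetal samples).
#'
#' @param config the [sim_config()] used for [simulate_pair()].
#' @param truth the `truth` tibble returned by [simulate_pair()].
#' @return A duo tibble for [wlm_adjust()], plus the true `b` per SNP in
#'   column `b_true`.
#' @export
simulate_duos <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(truth, c("rsid", "maf", "maternal_direct"), "simulation truth")
  withr::with_seed(config$seed + 1L, {
    k <- nrow(truth)
    b <- if (config$fetal_direct_sd > 0) {
      rnorm(k, 0, config$fetal_direct_sd)
    } else {
      rep(0, k)
    }
    a <- truth$maternal_direct
    se <- gwas_se(truth$maf, config$n_out, config$case_fraction_out)
    tibble(
      rsid = truth$rsid,
      beta_m = rnorm(k, a + b / 2, se), se_m = se,
      beta_f = rnorm(k, b + a / 2, se), se_f = se,
      cov_mf = 0,
      b_true = b
    )
  })
}

#' Split a pooled outcome dataset into per-study datasets
#'
#' Emulates a multi-study outcome meta-analysis in reverse: study `s` with
#' weight `w_s` reports the pooled effect plus noise at precision
#' `se / sqrt(w_s)`, so the fixed-effect meta-analysis of the splits
#' reproduces the pooled precision exactly and the pooled estimate in
#' expectation.
#'
#' @param outcome pooled outcome summary-statistics tibble.
#' @param n_studies number of studies (>= 2).
#' @param weights study precision shares, positive, summing to 1; default
#'   equal.
#' @param seed integer seed.
#' @return A named list of per-study summary-statistics tibbles.
#' @export
split_studies <- function(outcome, n_studies, weights = NULL, seed) {
  assert_columns(outcome, summary_stats_cols, "outcome dataset")
  if (n_studies < 2) {
    abort("n_studies must be >= 2", class = "mrliability_config_error")
  }
  weights <- weights %||% rep(1 / n_studies, n_studies)
  if (length(weights) != n_studies || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort("weights must be positive and sum to 1",
          class = "mrliability_config_error")
  }
  withr::with_seed(as.integer(seed), {
    setNames(lapply(seq_len(n_studies), function(s) {
      st <- outcome
      st$se <- outcome$se / sqrt(weights[s])
      st$beta <- rnorm(nrow(outcome), outcome$beta, st$se)
      st$pval <- pmax(z_pvalue(st$beta, st$se), .Machine$double.xmin)
      st$n <- round(outcome$n * weights[s])
      st$n_case <- round(outcome$n_case * weights[s])
      st$n_control <- st$n - st$n_case
      st
    }), paste0("study_", seq_len(n_studies)))
  })
}
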