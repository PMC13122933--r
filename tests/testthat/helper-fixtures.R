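# fixture builders and independent oracles shared across test files

toy_stats <- function(rsid, effect_allele, other_allele, beta, se,
                      pval = NULL, eaf = NA_real_, chrom = NA, pos = NA,
                      n = NA_real_, n_case = NA_real_, n_control = NA_real_,
                      trait_id = "trait", trait_type = "binary") {
  pval <- pval %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  as_summary_stats(
    tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                   effect_allele = effect_allele, other_allele = other_allele,
                   eaf = eaf, beta = beta, se = se, pval = pval,
                   n = n, n_case = n_case, n_control = n_control),
    trait_id = trait_id, trait_type = trait_type)
}

# harmonized-table builder: already aligned pairs, disposition kept
toy_pairs <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                      rsid = NULL, chrom = "1", pos = NULL,
                      n_exp = 5e4, n_out = 1e5,
                      condition_id = "cond", outcome_id = "outc",
                      outcome_type = "binary") {
  k <- length(beta_exp)
  rsid <- rsid %||% sprintf("rs%d", seq_len(k))
  pos <- pos %||% as.integer(seq_len(k) * 1e6)
  tibble::tibble(
    condition_id = condition_id, outcome_id = outcome_id,
    rsid = rsid, chrom = rep_len(chrom, k), pos = pos,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    pval_exp = pmax(2 * pnorm(-abs(beta_exp / rep_len(se_exp, k))), 1e-300),
    eaf_exp = 0.3,
    n_exp = rep_len(n_exp, k), n_case_exp = NA_real_, n_control_exp = NA_real_,
    beta_out = beta_out, se_out = rep_len(se_out, k),
    pval_out = pmax(2 * pnorm(-abs(beta_out / rep_len(se_out, k))), 1e-300),
    eaf_out = 0.3,
    n_out = rep_len(n_out, k), n_case_out = NA_real_, n_control_out = NA_real_,
    outcome_type = outcome_type,
    disposition = "kept"
  )
}

`%||%` <- rlang::`%||%`

# --- independent oracles -------------------------------------------------

# IVW as a zero-intercept weighted regression solved in closed form
oracle_ivw_slope <- function(bx, by, se_out) {
  w <- 1 / se_out^2
  sum(w * bx * by) / sum(w * bx^2)
}

# weighted-mean-of-ratios form, for cross-checking the identity
oracle_ivw_weighted_mean <- function(bx, by, se_out) {
  w <- bx^2 / se_out^2
  theta <- by / bx
  list(beta = sum(w * theta) / sum(w),
       se_fixed = 1 / sqrt(sum(w)),
       q = sum(w * (theta - sum(w * theta) / sum(w))^2))
}

# general weighted least squares with intercept by normal equations
oracle_wls <- function(bx, by, w) {
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * by)
  est <- solve(XtWX, XtWy)
  fitted <- X %*% est
  rss_w <- sum(w * (by - fitted)^2)
  list(intercept = est[1], slope = est[2],
       rss_w = rss_w, xtwx_inv = solve(XtWX))
}

# brute-force weighted median: sorted cumulative-weight grid + interpolation
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  i <- max(which(s < 0.5))
  theta[i] + (theta[i + 1] - theta[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# step-up Benjamini-Yekutieli, written out longhand
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  raw <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# greedy clump oracle: direct transcription of the stated procedure
oracle_clump <- function(df, ld, r2_thr, window_bp) {
  df <- df[order(df$pval, df$rsid), ]
  keep <- character(0)
  while (nrow(df) > 0) {
    best <- df[1, ]
    keep <- c(keep, best$rsid)
    drop <- vapply(seq_len(nrow(df)), function(i) {
      if (i == 1) return(TRUE)
      if (df$chrom[i] != best$chrom) return(FALSE)
      if (abs(df$pos[i] - best$pos) > window_bp) return(FALSE)
      r2 <- if (!is.null(ld) && df$rsid[i] %in% rownames(ld) &&
                best$rsid %in% rownames(ld)) ld[df$rsid[i], best$rsid] else 1
      r2 >= r2_thr
    }, logical(1))
    df <- df[!drop, ]
  }
  keep
}
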