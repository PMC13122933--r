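new_mr_fit <- function(method, pairs, beta, se, pval,
                       q = NA_real_, q_df = NA_real_, q_pval = NA_real_,
                       intercept = NA_real_, intercept_se = NA_real_,
                       intercept_pval = NA_real_,
                       scale = "per_logodds", adjustment = "none") {
  structure(
    list(
      method = method,
      condition_id = pairs$condition_id[1] %||% NA_character_,
      outcome_id = pairs$outcome_id[1] %||% NA_character_,
      outcome_type = pairs$outcome_type[1] %||% "binary",
      n_snp = nrow(pairs),
      beta = beta, se = se,
      ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
      pval = pval,
      q = q, q_df = q_df, q_pval = q_pval,
      intercept = intercept, intercept_se = intercept_se,
      intercept_pval = intercept_pval,
      scale = scale,
      adjustment = adjustment,
      data = pairs
    ),
    class = "mr_fit"
  )
}

check_pairs <- function(pairs, min_snp, method) {
  assert_columns(pairs, c("rsid", "beta_exp", "se_exp", "beta_out", "se_out"),
                 "harmonized pairs")
  if ("disposition" %in% names(pairs)) {
    pairs <- harmonized_pairs(pairs)
  }
  if (nrow(pairs) < min_snp) {
    abort(sprintf("%s requires at least %d instrument(s); got %d",
                  method, min_snp, nrow(pairs)),
          class = "mrliability_insufficient_instruments")
  }
  if (any(pairs$se_exp <= 0 | pairs$se_out <= 0, na.rm = TRUE)) {
    abort("standard errors must be > 0", class = "mrliability_input_error")
  }
  pairs
}

#' Wald ratio causal estimate from a single instrument
#'
#' The single-instrument estimate `beta_out / beta_exp` with the first-order
#' standard error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param pairs harmonized table with exactly one retained row.
#' @return An `mr_fit` object (see [tidy.mr_fit()]).
#' @export
mr_wald_ratio <- function(pairs) {
  pairs <- check_pairs(pairs, 1, "the Wald ratio")
  if (nrow(pairs) > 1) {
    abort("the Wald ratio takes a single instrument; use mr_ivw() for several",
          class = "mrliability_input_error")
  }
  if (pairs$beta_exp == 0) {
    abort("Wald ratio undefined: instrument has zero exposure effect",
          class = "mrliability_input_error")
  }
  beta <- pairs$beta_out / pairs$beta_exp
  se <- pairs$se_out / abs(pairs$beta_exp)
  new_mr_fit("wald", pairs, beta, se, z_pvalue(beta, se))
}

#' Multiplicative random-effects inverse-variance-weighted estimate
#'
#' Pools per-instrument Wald ratios with first-order weights
#' `w_j = beta_exp_j^2 / se_out_j^2` (equivalent to a zero-intercept weighted
#' regression of outcome effects on exposure effects). Heterogeneity is
#' summarised by Cochran's Q on `n_snp - 1` degrees of freedom, and the
#' fixed-effect standard error `(sum w_j)^(-1/2)` is inflated by
#' `max(1, sqrt(Q / df))` — the multiplicative random-effects model with the
#' overdispersion factor floored at 1. P-values use the normal
#' approximation.
#'
#' @param pairs harmonized table with at least two retained instruments;
#'   instruments with `beta_exp = 0` are excluded with a warning.
#' @return An `mr_fit` object.
#' @export
mr_ivw <- function(pairs) {
  pairs <- check_pairs(pairs, 2, "IVW")
  if (any(pairs$beta_exp == 0)) {
    warn(sprintf("excluding %d instrument(s) with zero exposure effect",
                 sum(pairs$beta_exp == 0)))
    pairs <- pairs |> filter(.data$beta_exp != 0)
    if (nrow(pairs) < 2) {
      abort("fewer than 2 usable instruments remain; use mr_wald_ratio()",
            class = "mrliability_insufficient_instruments")
    }
  }
  w <- pairs$beta_exp^2 / pairs$se_out^2
  theta <- pairs$beta_out / pairs$beta_exp
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  q_df <- nrow(pairs) - 1
  se <- se_fixed * max(1, sqrt(q / q_df))
  new_mr_fit("ivw_re", pairs, beta, se, z_pvalue(beta, se),
             q = q, q_df = q_df, q_pval = pchisq(q, q_df, lower.tail = FALSE))
}

#' MR-Egger regression with intercept test
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `1 / se_out^2`), after orienting every instrument so
#' its exposure effect is positive. The slope is the pleiotropy-robust
#' causal estimate; a non-zero intercept indicates unbalanced horizontal
#' pleiotropy. Both standard errors carry the residual overdispersion factor
#' `max(1, sqrt(RSS_w / (n_snp - 2)))`; inference uses the t distribution on
#' `n_snp - 2` degrees of freedom. The weighted residual sum of squares
#' doubles as the heterogeneity Q on `n_snp - 2` degrees of freedom.
#'
#' @param pairs harmonized table with at least three retained instruments.
#' @return An `mr_fit` object with `intercept`, `intercept_se`,
#'   `intercept_pval` populated.
#' @export
mr_egger <- function(pairs) {
  pairs <- check_pairs(pairs, 3, "MR-Egger")
  sgn <- ifelse(pairs$beta_exp < 0, -1, 1)
  bx <- pairs$beta_exp * sgn
  by <- pairs$beta_out * sgn
  w <- 1 / pairs$se_out^2
  fit <- lm(by ~ bx, weights = w)
  k <- nrow(pairs)
  rss_w <- sum(w * resid(fit)^2)
  sigma2 <- rss_w / (k - 2)
  # unscaled (X'WX)^-1 standard errors with the overdispersion floor
  X <- cbind(1, bx)
  se_raw <- sqrt(diag(solve(t(X) %*% (w * X))))
  infl <- max(1, sqrt(sigma2))
  slope <- unname(coef(fit)[2])
  slope_se <- unname(se_raw[2]) * infl
  icpt <- unname(coef(fit)[1])
  icpt_se <- unname(se_raw[1]) * infl
  new_mr_fit("egger", pairs, slope, slope_se,
             2 * pt(-abs(slope / slope_se), df = k - 2),
             q = rss_w, q_df = k - 2,
             q_pval = pchisq(rss_w, k - 2, lower.tail = FALSE),
             intercept = icpt, intercept_se = icpt_se,
             intercept_pval = 2 * pt(-abs(icpt / icpt_se), df = k - 2))
}

weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-instrument Wald ratios (weights
#' `beta_exp^2 / se_out^2`, normalised), obtained by linear interpolation of
#' the sorted ratios at cumulative weight 0.5. Consistent when instruments
#' carrying at least half the weight are valid. The standard error comes
#' from a seeded parametric bootstrap: exposure and outcome effects are
#' redrawn from normal distributions centred on the observed values with
#' their reported standard errors, and the estimate is recomputed per draw.
#'
#' @param pairs harmonized table with at least three retained instruments.
#' @param n_boot number of bootstrap draws, default 1000.
#' @param seed integer seed for the bootstrap (required, for
#'   reproducibility).
#' @return An `mr_fit` object.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed) {
  pairs <- check_pairs(pairs, 3, "the weighted median")
  if (missing(seed)) {
    abort("`seed` is required for the weighted-median bootstrap",
          class = "mrliability_config_error")
  }
  w <- pairs$beta_exp^2 / pairs$se_out^2
  beta <- weighted_median_point(pairs$beta_out / pairs$beta_exp, w)
  k <- nrow(pairs)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(k, pairs$beta_exp, pairs$se_exp)
      by <- rnorm(k, pairs$beta_out, pairs$se_out)
      weighted_median_point(by / bx, bx^2 / pairs$se_out^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_fit("weighted_median", pairs, beta, se, z_pvalue(beta, se))
}

#' Rescale a causal estimate to a doubling of liability
#'
#' Exposure effects for binary conditions are on the log-odds liability
#' scale; a one-unit increase is a large, hard-to-interpret shift.
#' Multiplying the estimate and its standard error by `ln 2` re-expresses
#' the effect per doubling of the odds of liability. Confidence intervals
#' are re-derived as `beta +/- 1.96 se` on the scaled values, and the
#' p-value is unchanged (the z-statistic is invariant to a positive scalar).
#'
#' @param fit an `mr_fit` on the per-log-odds scale.
#' @return The fit with `scale = "per_doubling"`; for binary outcomes the
#'   odds-ratio surface is `exp(beta)`, `exp(ci_low)`, `exp(ci_high)` (see
#'   [tidy.mr_fit()]).
#' @export
scale_to_doubling <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  if (identical(fit$scale, "per_doubling")) {
    abort("estimate is already on the per-doubling scale",
          class = "mrliability_state_error")
  }
  fit$beta <- fit$beta * log(2)
  fit$se <- fit$se * log(2)
  fit$ci_low <- fit$beta - 1.96 * fit$se
  fit$ci_high <- fit$beta + 1.96 * fit$se
  fit$scale <- "per_doubling"
  fit
}

#' Convert fitted MR objects to the fixed-layout results table
#'
#' @param fits an `mr_fit` or list of them (NULL entries are dropped).
#' @return A results tibble with the column order used by
#'   [write_results_table()]. `or_scaled` and its CI are `exp()` of the
#'   estimate, populated only for binary outcomes on the per-doubling scale.
#' @export
mr_results_table <- function(fits) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  fits <- purrr::compact(fits)
  purrr::map_dfr(fits, function(f) {
    binary_doubling <- identical(f$scale, "per_doubling") &&
      identical(f$outcome_type, "binary")
    tibble(
      condition = f$condition_id, outcome = f$outcome_id, method = f$method,
      n_snp = f$n_snp, beta = f$beta, se = f$se,
      ci_low = f$ci_low, ci_high = f$ci_high, pval = f$pval,
      or_scaled = if (binary_doubling) exp(f$beta) else NA_real_,
      or_ci_low = if (binary_doubling) exp(f$ci_low) else NA_real_,
      or_ci_high = if (binary_doubling) exp(f$ci_high) else NA_real_,
      q = f$q, q_df = f$q_df, q_pval = f$q_pval,
      intercept = f$intercept, intercept_se = f$intercept_se,
      intercept_pval = f$intercept_pval,
      scale = f$scale
    )
  })
}

#' Estimate causal effects for one condition-outcome pair
#'
#' Runs the requested estimators on a harmonized table and returns the
#' stacked results. With a single retained instrument only the Wald ratio is
#' computed; Egger and the weighted median are attempted only with three or
#' more instruments.
#'
#' @param pairs harmonized table for one condition-outcome pair.
#' @param methods subset of `c("ivw", "egger", "weighted_median")`.
#' @param scale `"per_doubling"` (default, effects per doubling of liability
#'   odds) or `"per_logodds"`.
#' @param seed integer seed for the weighted-median bootstrap.
#' @param n_boot bootstrap draws for the weighted median.
#' @return A results tibble (one row per method actually run).
#' @export
mr_estimate <- function(pairs, methods = c("ivw", "egger", "weighted_median"),
                        scale = c("per_doubling", "per_logodds"),
                        seed = 1L, n_boot = 1000) {
  scale <- match.arg(scale)
  methods <- match.arg(methods, several.ok = TRUE)
  retained <- if ("disposition" %in% names(pairs)) harmonized_pairs(pairs) else pairs
  k <- nrow(retained)
  fits <- list()
  if (k == 1) {
    fits$wald <- mr_wald_ratio(retained)
  } else if (k >= 2) {
    if ("ivw" %in% methods) fits$ivw <- mr_ivw(retained)
    if (k >= 3) {
      if ("egger" %in% methods) fits$egger <- mr_egger(retained)
      if ("weighted_median" %in% methods) {
        fits$wmedian <- mr_weighted_median(retained, n_boot = n_boot, seed = seed)
      }
    }
  } else {
    abort("no retained instruments for this condition-outcome pair",
          class = "mrliability_insufficient_instruments")
  }
  if (scale == "per_doubling") fits <- purrr::map(fits, scale_to_doubling)
  mr_results_table(fits)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit> %s: %s -> %s\n", x$method, x$condition_id, x$outcome_id))
  cat(sprintf("  %d instrument(s), scale: %s\n", x$n_snp, x$scale))
  cat(sprintf("  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (is.finite(x$q)) {
    cat(sprintf("  Cochran's Q = %.4g on %d df (p = %.3g)\n", x$q, x$q_df, x$q_pval))
  }
  if (is.finite(x$intercept)) {
    cat(sprintf("  Egger intercept = %.4g (se %.4g, p = %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' Tidy and summarise fitted MR objects
#'
#' `tidy()` returns the coefficient-level view (slope, and intercept for
#' MR-Egger) with confidence bounds; `glance()` returns the one-row model
#' summary with heterogeneity diagnostics.
#'
#' @param x an `mr_fit` object.
#' @param exponentiate return odds ratios instead of log-odds (binary
#'   outcomes).
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mr_fit <- function(x, exponentiate = FALSE, ...) {
  out <- tibble(
    term = "liability",
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pval,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
  if (is.finite(x$intercept)) {
    out <- bind_rows(out, tibble(
      term = "(intercept)",
      estimate = x$intercept, std.error = x$intercept_se,
      statistic = x$intercept / x$intercept_se, p.value = x$intercept_pval,
      conf.low = x$intercept - 1.96 * x$intercept_se,
      conf.high = x$intercept + 1.96 * x$intercept_se
    ))
  }
  if (exponentiate) {
    out <- out |> mutate(across(all_of(c("estimate", "conf.low", "conf.high")), exp))
  }
  out
}

#' @rdname tidy.mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble(
    condition = x$condition_id, outcome = x$outcome_id, method = x$method,
    n_snp = x$n_snp, q = x$q, q_df = x$q_df, q_pval = x$q_pval,
    scale = x$scale, adjustment = x$adjustment
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
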