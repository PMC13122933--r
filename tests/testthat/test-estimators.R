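test_that("Wald ratio matches the direct-division and normal-tail oracles", {
  f <- mr_wald_ratio(toy_pairs(0.5, 0.05, se_out = 0.01))
  expect_equal(f$beta, 0.10)
  expect_equal(f$se, 0.02)
  expect_equal(f$n_snp, 1)
  expect_true(is.na(f$q))

  expect_equal(mr_wald_ratio(toy_pairs(1.0, 0.0))$beta, 0)

  f2 <- mr_wald_ratio(toy_pairs(0.25, 0.02, se_out = 0.005))
  expect_equal(f2$beta, 0.08)
  expect_equal(f2$se, 0.02)
  expect_equal(f2$pval, 2 * pnorm(-4))

  expect_error(mr_wald_ratio(toy_pairs(0, 0.01)), "zero exposure effect")
})

test_that("IVW equals the weighted-mean and zero-intercept regression oracles", {
  # homogeneous ratios: Q = 0 and the fixed-effect se is untouched
  p <- toy_pairs(c(0.2, 0.4, 0.5), c(0.02, 0.04, 0.05), se_out = c(0.01, 0.02, 0.01))
  f <- mr_ivw(p)
  expect_equal(f$beta, 0.1)
  expect_equal(f$q, 0)
  expect_equal(f$se, 1 / sqrt(sum(p$beta_exp^2 / p$se_out^2)))
  expect_equal(f$q_df, 2)

  # two-instrument weighted mean: w = (1600, 625), beta = 130/2225
  p2 <- toy_pairs(c(0.4, 0.5), c(0.02, 0.04), se_out = c(0.01, 0.02))
  f2 <- mr_ivw(p2)
  expect_equal(f2$beta, 130 / 2225)

  expect_error(mr_ivw(toy_pairs(0.4, 0.02)), "at least 2")

  # randomized instances: equality with both algebraic forms
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    p3 <- toy_pairs(runif(k, 0.05, 0.5) * sample(c(-1, 1), k, TRUE),
                    rnorm(k, 0, 0.05), se_out = runif(k, 0.005, 0.05))
    f3 <- mr_ivw(p3)
    wm <- oracle_ivw_weighted_mean(p3$beta_exp, p3$beta_out, p3$se_out)
    expect_equal(f3$beta, wm$beta)
    expect_equal(f3$beta, oracle_ivw_slope(p3$beta_exp, p3$beta_out, p3$se_out))
    expect_equal(f3$q, wm$q)
    expect_equal(f3$se, wm$se_fixed * max(1, sqrt(wm$q / (k - 1))))
  }
})

test_that("instruments with zero exposure effect are excluded from IVW with a warning", {
  p <- toy_pairs(c(0.4, 0, 0.5), c(0.02, 0.01, 0.04), se_out = c(0.01, 0.01, 0.02))
  expect_warning(f <- mr_ivw(p), "zero exposure effect")
  expect_equal(f$n_snp, 2)
  expect_equal(f$beta, 130 / 2225)
})

test_that("Egger recovers exact linear and affine instrument relationships", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  f <- mr_egger(toy_pairs(bx, 0.1 * bx))
  expect_equal(f$beta, 0.1)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$q, 0, tolerance = 1e-12)

  f2 <- mr_egger(toy_pairs(bx, 0.02 + 0.1 * bx))
  expect_equal(f2$beta, 0.1)
  expect_equal(f2$intercept, 0.02)

  expect_error(mr_egger(toy_pairs(c(0.1, 0.2), c(0.01, 0.02))), "at least 3")
})

test_that("Egger matches a normal-equation WLS oracle with the overdispersion floor", {
  set.seed(17)
  for (rep in 1:8) {
    k <- sample(5:15, 1)
    p <- toy_pairs(runif(k, 0.05, 0.5), rnorm(k, 0, 0.03),
                   se_out = runif(k, 0.005, 0.05))
    f <- mr_egger(p)
    o <- oracle_wls(p$beta_exp, p$beta_out, 1 / p$se_out^2)
    expect_equal(f$beta, o$slope)
    expect_equal(f$intercept, o$intercept)
    expect_equal(f$q, o$rss_w)
    infl <- max(1, sqrt(o$rss_w / (k - 2)))
    expect_equal(f$se, sqrt(o$xtwx_inv[2, 2]) * infl)
    expect_equal(f$intercept_se, sqrt(o$xtwx_inv[1, 1]) * infl)
    expect_equal(f$pval, 2 * pt(-abs(f$beta / f$se), k - 2))
  }
})

test_that("weighted median interpolates the sorted cumulative-weight grid", {
  # symmetric equal-weight ratios
  p <- toy_pairs(c(1, 1, 1), c(0.1, 0.2, 0.3))
  expect_equal(mr_weighted_median(p, seed = 1)$beta, 0.2)

  # an outlier carrying under half the weight cannot move the estimate
  p2 <- toy_pairs(c(1, 1, 1, 1), c(0.1, 0.1, 0.1, 5.0))
  expect_equal(mr_weighted_median(p2, seed = 1)$beta, 0.1)

  # unequal weights against the brute-force oracle
  set.seed(23)
  for (rep in 1:8) {
    k <- sample(4:10, 1)
    p3 <- toy_pairs(runif(k, 0.1, 0.5), rnorm(k, 0, 0.05),
                    se_out = runif(k, 0.005, 0.05))
    f <- mr_weighted_median(p3, n_boot = 50, seed = rep)
    expect_equal(f$beta,
                 oracle_weighted_median(p3$beta_out / p3$beta_exp,
                                        p3$beta_exp^2 / p3$se_out^2))
  }

  # the bootstrap is seeded: identical seeds give identical standard errors
  f1 <- mr_weighted_median(p, n_boot = 200, seed = 42)
  f2 <- mr_weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(f1$se, f2$se)
  expect_error(mr_weighted_median(p), "seed")
})

test_that("homogeneous ratios collapse all estimators to the common ratio", {
  bx <- c(0.2, 0.3, 0.4, 0.5)
  p <- toy_pairs(bx, 0.07 * bx)
  expect_equal(mr_ivw(p)$beta, 0.07)
  expect_equal(mr_egger(p)$beta, 0.07)
  expect_equal(mr_weighted_median(p, seed = 3)$beta, 0.07)
  expect_equal(mr_ivw(p)$q, 0, tolerance = 1e-12)
})

test_that("negating outcome effects negates estimates but not uncertainty", {
  set.seed(5)
  p <- toy_pairs(runif(6, 0.1, 0.5), rnorm(6, 0.02, 0.02),
                 se_out = runif(6, 0.01, 0.03))
  n <- p
  n$beta_out <- -n$beta_out
  for (pairfit in list(list(mr_ivw(p), mr_ivw(n)),
                       list(mr_egger(p), mr_egger(n)))) {
    expect_equal(pairfit[[1]]$beta, -pairfit[[2]]$beta)
    expect_equal(pairfit[[1]]$se, pairfit[[2]]$se)
    expect_equal(pairfit[[1]]$q, pairfit[[2]]$q)
  }
  expect_equal(mr_egger(p)$intercept, -mr_egger(n)$intercept)
})

test_that("per-doubling rescaling multiplies by ln 2 and preserves the p-value", {
  f <- mr_ivw(toy_pairs(c(0.4, 0.5), c(0.02, 0.04), se_out = c(0.01, 0.02)))
  f$beta <- 0.1
  f$se <- 0.05
  s <- scale_to_doubling(f)
  expect_equal(s$beta, 0.1 * log(2))
  expect_equal(s$se, 0.05 * log(2))
  expect_equal(s$pval, f$pval)
  expect_equal(s$scale, "per_doubling")
  # closed-form odds-ratio surface
  row <- mr_results_table(s)
  expect_equal(row$or_scaled, exp(0.1 * log(2)), tolerance = 1e-6)
  expect_equal(row$or_ci_low, exp(0.1 * log(2) - 1.96 * 0.05 * log(2)), tolerance = 1e-6)
  expect_equal(row$or_ci_high, exp(0.1 * log(2) + 1.96 * 0.05 * log(2)), tolerance = 1e-6)
  expect_equal(round(c(row$or_scaled, row$or_ci_low, row$or_ci_high), 4),
               c(1.0718, 1.0014, 1.1471))
  expect_error(scale_to_doubling(s), "already")

  # the null is scale-invariant
  f0 <- mr_ivw(toy_pairs(c(0.4, 0.5), c(0, 0), se_out = c(0.01, 0.02)))
  s0 <- scale_to_doubling(f0)
  expect_equal(s0$beta, 0)
  expect_equal(mr_results_table(s0)$or_scaled, 1)
})

test_that("tidy and glance expose broom-style views of a fit", {
  p <- toy_pairs(c(0.2, 0.3, 0.4, 0.5), c(0.021, 0.028, 0.042, 0.05))
  f <- mr_egger(p)
  td <- tidy(f)
  expect_equal(td$term, c("liability", "(intercept)"))
  expect_equal(td$estimate[1], f$beta)
  expect_equal(tidy(f, exponentiate = TRUE)$estimate[1], exp(f$beta))
  gl <- glance(f)
  expect_equal(gl$n_snp, 4)
  expect_equal(gl$method, "egger")
  expect_s3_class(autoplot(f), "ggplot")
})
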