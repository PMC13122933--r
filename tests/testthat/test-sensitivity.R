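steiger_pairs <- function(z_exp, n_exp, z_out, n_out) {
  toy_pairs(beta_exp = z_exp * 0.01, beta_out = z_out * 0.01,
            se_exp = 0.01, se_out = 0.01, n_exp = n_exp, n_out = n_out)
}

test_that("Steiger filtering removes only significantly outcome-first SNPs", {
  # exposure variance dominates: retained
  sf <- steiger_filter(steiger_pairs(10, 5e4, 1, 1e5))
  expect_true(sf$records$direction_ok)
  expect_false(sf$records$removed)
  expect_equal(nrow(sf$retained), 1)

  # exact tie: not strictly worse, retained
  sf2 <- steiger_filter(steiger_pairs(5, 1e4, 5, 1e4))
  expect_true(sf2$records$direction_ok)
  expect_false(sf2$records$removed)

  # strongly outcome-first: removed, p-value matches the closed-form oracle
  sf3 <- steiger_filter(steiger_pairs(1, 1e4, 20, 1e4))
  expect_true(sf3$records$removed)
  r_exp <- 1 / sqrt(1 + 1e4)
  r_out <- 20 / sqrt(400 + 1e4)
  z <- (atanh(r_exp) - atanh(r_out)) / sqrt(1 / (1e4 - 3) + 1 / (1e4 - 3))
  expect_equal(sf3$records$steiger_pval, pnorm(z))
  expect_equal(nrow(sf3$retained), 0)
})

test_that("Steiger filtering never removes a SNP explaining at least as much exposure variance", {
  set.seed(19)
  for (rep in 1:20) {
    k <- 8
    p <- toy_pairs(rnorm(k, 0.1, 0.05), rnorm(k, 0, 0.03),
                   se_exp = 0.01, se_out = 0.01,
                   n_exp = sample(c(5e3, 5e4), 1), n_out = sample(c(1e4, 2e5), 1))
    sf <- steiger_filter(p)
    expect_false(any(sf$records$removed & sf$records$r2_exp >= sf$records$r2_out))
  }
})

test_that("unevaluable sample sizes retain the SNP with a flag", {
  p <- steiger_pairs(1, 2, 20, 1e4)  # n_exp <= 3
  expect_message(sf <- steiger_filter(p), "unevaluable")
  expect_true(sf$records$unevaluable)
  expect_false(sf$records$removed)
  expect_equal(nrow(sf$retained), 1)
})

test_that("leave-one-SNP-out flags exactly a planted outlier", {
  # homogeneous ratios: every omission is the same, nothing influential
  bx <- c(0.2, 0.3, 0.4, 0.5)
  loo <- leave_one_snp_out(toy_pairs(bx, 0.1 * bx))
  expect_equal(nrow(loo), 4)
  expect_true(all(abs(loo$delta_vs_full) < 1e-12))
  expect_false(any(loo$influential))

  # one planted outlier ratio: only that SNP's omission moves the estimate
  p <- toy_pairs(c(0.3, 0.3, 0.3, 0.3), c(0.03, 0.03, 0.03, 0.3))
  loo2 <- leave_one_snp_out(p)
  expect_equal(loo2$omitted_id[loo2$influential], "rs4")
  # every omission is verified against the weighted-mean oracle
  for (i in 1:4) {
    o <- oracle_ivw_weighted_mean(p$beta_exp[-i], p$beta_out[-i], p$se_out[-i])
    expect_equal(loo2$beta[loo2$omitted_id == p$rsid[i]], o$beta)
  }

  # the count contract at the minimum size
  loo3 <- leave_one_snp_out(toy_pairs(c(0.2, 0.3, 0.4), c(0.02, 0.03, 0.04)))
  expect_equal(nrow(loo3), 3)
  expect_true(all(loo3$n_snp == 2))
  expect_error(leave_one_snp_out(toy_pairs(c(0.2, 0.3), c(0.02, 0.03))), "at least 3")
})

test_that("fixed-effect meta-analysis of identical studies halves the variance", {
  s <- toy_stats(c("rs1", "rs2", "rs3"), "A", "G", c(0.02, 0.03, 0.04), 0.01,
                 eaf = 0.2, chrom = "1", pos = c(1e6, 2e6, 3e6),
                 n = 1000, trait_id = "outc")
  pooled <- meta_analyze_studies(list(a = s, b = s))
  expect_equal(pooled$beta, s$beta)
  expect_equal(pooled$se, s$se / sqrt(2))
})

test_that("leave-one-study-out reruns IVW on the re-meta-analysed remainder", {
  exposure <- toy_stats(c("rs1", "rs2", "rs3"), "A", "G", c(0.2, 0.3, 0.4), 0.01,
                        eaf = 0.2, chrom = "1", pos = c(1e6, 2e6, 3e6),
                        trait_id = "cond")
  s <- toy_stats(c("rs1", "rs2", "rs3"), "A", "G", c(0.02, 0.03, 0.04), 0.01,
                 eaf = 0.2, chrom = "1", pos = c(1e6, 2e6, 3e6),
                 n = 1000, trait_id = "outc")
  # two identical studies: omitting either reproduces the single-study IVW
  loo <- leave_one_study_out(list(a = s, b = s), exposure)
  single <- mr_ivw(harmonized_pairs(harmonize(exposure, s)))
  expect_equal(loo$beta, rep(single$beta, 2))
  expect_equal(loo$omitted_id, c("a", "b"))

  # a study with inverted effects: omitting it moves the estimate to the clean value
  inverted <- s |> dplyr::mutate(beta = -beta)
  loo2 <- leave_one_study_out(list(a = s, b = s, c = inverted), exposure)
  clean <- loo2$beta[loo2$omitted_id == "c"]
  expect_equal(clean, single$beta)
  expect_true(all(abs(loo2$beta[loo2$omitted_id != "c"]) < abs(clean)))

  # a SNP covered only by the omitted study disappears from that replicate
  s_small <- s[1:2, ]
  loo3 <- leave_one_study_out(list(big = s, small = s_small), exposure)
  # omitting 'big' leaves only the 2-SNP study
  expect_equal(loo3$n_snp[loo3$omitted_id == "big"], 2)
  expect_equal(loo3$n_snp[loo3$omitted_id == "small"], 3)

  expect_error(leave_one_study_out(list(a = s), exposure), "at least two")
})

test_that("the omit-none meta-analysis control equals IVW on the pooled data", {
  set.seed(3)
  exposure <- toy_stats(sprintf("rs%d", 1:5), "A", "G", runif(5, 0.1, 0.4), 0.01,
                        eaf = 0.2, chrom = "1", pos = (1:5) * 1e6, trait_id = "cond")
  studies <- lapply(1:3, function(s) {
    toy_stats(sprintf("rs%d", 1:5), "A", "G", rnorm(5, 0.02, 0.01),
              runif(5, 0.01, 0.03), eaf = 0.2, chrom = "1", pos = (1:5) * 1e6,
              n = 1000, trait_id = "outc")
  })
  names(studies) <- c("a", "b", "c")
  pooled <- meta_analyze_studies(studies)
  fit_pooled <- mr_ivw(harmonized_pairs(harmonize(exposure, pooled)))
  # per-SNP meta then IVW, computed longhand
  beta_meta <- sapply(1:5, function(i) {
    b <- sapply(studies, function(s) s$beta[i])
    se <- sapply(studies, function(s) s$se[i])
    sum(b / se^2) / sum(1 / se^2)
  })
  se_meta <- sapply(1:5, function(i) {
    se <- sapply(studies, function(s) s$se[i])
    1 / sqrt(sum(1 / se^2))
  })
  o <- oracle_ivw_weighted_mean(exposure$beta, beta_meta, se_meta)
  expect_equal(fit_pooled$beta, o$beta)
})

test_that("HLA-excluded reruns drop the flagged instruments", {
  p <- toy_pairs(c(0.2, 0.3, 0.4), c(0.02, 0.03, 0.04),
                 chrom = c("1", "6", "2"), pos = c(1e6, 30000000L, 2e6))
  # rs2 sits inside the HLA window
  fit <- rerun_without_hla(p)
  expect_equal(fit$n_snp, 2)
  o <- oracle_ivw_weighted_mean(p$beta_exp[-2], p$beta_out[-2], p$se_out[-2])
  expect_equal(fit$beta, o$beta)

  # no HLA SNPs: identical to the full IVW
  p_clean <- toy_pairs(c(0.2, 0.3, 0.4), c(0.02, 0.03, 0.04))
  expect_equal(rerun_without_hla(p_clean)$beta, mr_ivw(p_clean)$beta)

  # all SNPs in HLA: absent-result marker
  p_all <- toy_pairs(c(0.2, 0.3), c(0.02, 0.03), chrom = "6",
                     pos = c(29000000L, 30000000L))
  expect_warning(res <- rerun_without_hla(p_all), "HLA")
  expect_null(res)

  # a single survivor falls back to the Wald ratio
  p_one <- toy_pairs(c(0.2, 0.3), c(0.02, 0.03), chrom = c("1", "6"),
                     pos = c(1e6, 30000000L))
  expect_equal(rerun_without_hla(p_one)$method, "wald")
})
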