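exp_one <- function(ea = "A", oa = "G", beta = 0.10, eaf = NA_real_) {
  toy_stats("rs1", ea, oa, beta, 0.01, eaf = eaf, trait_id = "cond")
}
out_one <- function(ea, oa, beta, eaf = NA_real_) {
  toy_stats("rs1", ea, oa, beta, 0.02, eaf = eaf, trait_id = "outc")
}

test_that("swapped allele orientation flips the outcome beta and frequency", {
  h <- harmonize(exp_one("A", "G", 0.10), out_one("G", "A", -0.05, eaf = 0.8))
  expect_equal(h$disposition, "flipped")
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.2)
  expect_equal(h$effect_allele, "A")
  expect_equal(h$other_allele, "G")
})

test_that("strand-complemented alleles are corrected, in both orientations", {
  # T/C is A/G read from the opposite strand: no sign change
  h <- harmonize(exp_one("A", "G", 0.10), out_one("T", "C", 0.07))
  expect_equal(h$disposition, "strand_corrected")
  expect_equal(h$beta_out, 0.07)
  # C/T is complement + swap: sign change
  h2 <- harmonize(exp_one("A", "G", 0.10), out_one("C", "T", 0.07))
  expect_equal(h2$disposition, "strand_corrected")
  expect_equal(h2$beta_out, -0.07)
})

test_that("palindromic variants are adjudicated by allele frequency", {
  # both minor-allele frequencies informative and on the same side: kept
  h <- harmonize(exp_one("A", "T", 0.10, eaf = 0.10), out_one("A", "T", 0.04, eaf = 0.12))
  expect_equal(h$disposition, "kept")
  expect_equal(h$beta_out, 0.04)
  # opposite sides of 0.5: the outcome effect refers to the other allele
  h2 <- harmonize(exp_one("A", "T", 0.10, eaf = 0.10), out_one("A", "T", 0.04, eaf = 0.88))
  expect_equal(h2$disposition, "flipped")
  expect_equal(h2$beta_out, -0.04)
  expect_equal(h2$eaf_out, 0.12)
  # frequency uninformative (at 0.5, or above the threshold): dropped
  h3 <- harmonize(exp_one("C", "G", 0.10, eaf = 0.50), out_one("C", "G", 0.04, eaf = 0.10))
  expect_equal(h3$disposition, "dropped_palindromic")
  h4 <- harmonize(exp_one("C", "G", 0.10, eaf = 0.45), out_one("C", "G", 0.04, eaf = 0.45),
                  palindromic_maf_threshold = 0.42)
  expect_equal(h4$disposition, "dropped_palindromic")
})

test_that("irreconcilable pairs and absent variants get audit dispositions, not errors", {
  h <- harmonize(exp_one("A", "G", 0.10), out_one("A", "C", 0.05))
  expect_equal(h$disposition, "dropped_mismatch")
  exp2 <- toy_stats(c("rs1", "rs2"), "A", "G", c(0.1, 0.2), 0.01, trait_id = "cond")
  h2 <- harmonize(exp2, out_one("A", "G", 0.05))
  expect_setequal(h2$disposition, c("kept", "missing"))
  # disposition counts sum to the number of instrument rsids
  expect_equal(sum(harmonization_audit(h2)$n_snp), nrow(exp2))
  expect_equal(nrow(harmonized_pairs(h2)), 1)
})

test_that("harmonizing an already-aligned dataset is a no-op (involution safety)", {
  exposure <- toy_stats(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "T", "C"),
                        c(0.1, -0.2, 0.15), 0.01, eaf = c(0.2, 0.3, 0.4),
                        trait_id = "cond")
  outcome <- toy_stats(c("rs1", "rs2", "rs3"), c("A", "C", "T"), c("G", "T", "C"),
                       c(0.01, -0.02, 0.015), 0.02, eaf = c(0.2, 0.3, 0.4),
                       trait_id = "outc")
  h <- harmonize(exposure, outcome)
  expect_true(all(h$disposition == "kept"))
  expect_equal(h$beta_out, outcome$beta)
  expect_equal(h$eaf_out, outcome$eaf)
})

test_that("relabelling every outcome effect allele leaves retained effects unchanged", {
  set.seed(101)
  k <- 20
  alleles <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  pick <- sample(4, k, replace = TRUE)
  ea <- vapply(pick, function(i) alleles[[i]][1], character(1))
  oa <- vapply(pick, function(i) alleles[[i]][2], character(1))
  eaf <- runif(k, 0.05, 0.40)
  exposure <- toy_stats(sprintf("rs%d", 1:k), ea, oa, rnorm(k, 0, 0.1), 0.01,
                        eaf = eaf, trait_id = "cond")
  outcome <- toy_stats(sprintf("rs%d", 1:k), ea, oa, rnorm(k, 0, 0.02), 0.02,
                       eaf = eaf, trait_id = "outc")
  relabelled <- outcome
  relabelled$effect_allele <- outcome$other_allele
  relabelled$other_allele <- outcome$effect_allele
  relabelled$beta <- -outcome$beta
  relabelled$eaf <- 1 - outcome$eaf
  h1 <- harmonized_pairs(harmonize(exposure, outcome))
  h2 <- harmonized_pairs(harmonize(exposure, relabelled))
  expect_equal(h1$rsid, h2$rsid)
  expect_equal(h1$beta_exp, h2$beta_exp)
  expect_equal(h1$beta_out, h2$beta_out)
})

test_that("pre-harmonized tables load as kept pairs grouped per condition-outcome", {
  df <- tibble::tibble(
    condition = rep(c("c1", "c2"), each = 3),
    outcome = "o1",
    rsid = rep(c("rs1", "rs2", "rs3"), 2),
    effect_allele = "A", other_allele = "G",
    beta_exp = 0.1, se_exp = 0.01,
    beta_out = 0.01, se_out = 0.02
  )
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  h <- read_harmonized_table(path)
  expect_equal(nrow(h), 6)
  expect_true(all(h$disposition == "kept"))
  groups <- dplyr::group_split(h, condition_id, outcome_id)
  expect_length(groups, 2)
  expect_true(all(vapply(groups, nrow, integer(1)) == 3))
  # singleton collection
  h1 <- read_harmonized_table({
    p <- tempfile(fileext = ".tsv")
    readr::write_tsv(df[df$condition == "c1", ], p, progress = FALSE)
    p
  })
  expect_length(dplyr::group_split(h1, condition_id, outcome_id), 1)
  expect_error(read_harmonized_table({
    p <- tempfile(fileext = ".tsv")
    readr::write_tsv(df[, -6], p, progress = FALSE)
    p
  }), "beta_exp")
})
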