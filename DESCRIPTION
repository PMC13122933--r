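Package: mrliability
Title: Two-Sample Mendelian Randomization for Genetic Liability to Binary Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    of genetic liability to binary conditions on downstream outcomes, built
    around GWAS summary statistics. Implements instrument selection with
    greedy p-value-ranked LD clumping, allele harmonization with palindromic
    inference, inverse-variance-weighted, MR-Egger and weighted-median
    estimators with per-doubling-of-liability rescaling, Steiger
    directionality filtering, leave-one-SNP-out and leave-one-study-out
    sensitivity loops, HLA-region exclusion, adjustment of maternal
    SNP-outcome associations for fetal genotype via a weighted linear model,
    a two-tier follow-up selection rule with Benjamini-Yekutieli false
    discovery rate control, and a seeded synthetic summary-statistics
    generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    withr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
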