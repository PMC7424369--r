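Package: reopair
Title: Within-Sample Relative Expression Ordering Analysis of Confounders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how confounding factors (age, smoking, sex, race)
    perturb within-sample relative expression orderings (REOs) of gene pairs
    in transcriptomes. Detects significantly stable gene pairs per sample
    group with a one-tailed binomial test and Benjamini-Hochberg correction,
    compares groups through concordant/reversal pair classification and the
    reversal ratio, calls population-level differentially expressed genes
    with a RankCompV2-style iterative Fisher-exact procedure, tests per-pair
    age association with the Mann-Whitney U test and categorical confounder
    balance with Fisher's exact test, and performs hypergeometric gene-set
    enrichment from GMT files. Ships a synthetic-data generator that emulates
    the rank-template structure of normal-tissue transcriptomes so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
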