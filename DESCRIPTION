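Package: insomniamr
Title: Two-Sample Mendelian Randomization for Insomnia and Pregnancy Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization (MR) of
    genetic susceptibility to insomnia on pregnancy and perinatal outcomes.
    Provides summary-statistic input/output and preparation (allele
    harmonization, linkage-disequilibrium pruning, minor-allele-frequency
    filtering), the inverse-variance-weighted, MR-Egger and weighted-median
    causal estimators, heterogeneity, pleiotropy, directionality (Steiger) and
    instrument-strength diagnostics, individual-level association stages
    including a split cross-over design and a confounder-adjusted
    multivariable-regression comparator, fixed-effects cross-study
    meta-analysis with leave-one-out sensitivity analyses, and a seeded
    synthetic-data generator so every stage is testable without restricted
    cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
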