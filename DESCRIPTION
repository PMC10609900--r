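Package: caffemr
Title: Two-Sample Mendelian Randomization of Caffeine Exposures on Kidney Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian randomization
    (MR) with cis-instruments, built around the analysis of genetically
    predicted plasma caffeine level and caffeine intake on kidney function
    traits. Provides summary-statistics ingestion and validation, allele
    harmonization (swaps, strand flips, palindromes), gene-region instrument
    selection with optional LD pruning, per-variant Wald ratios, fixed- and
    random-effects inverse-variance-weighted pooling with heterogeneity
    statistics, forest-plot reporting, and synthetic-data generators --
    including a mechanistic metabolizer-compensation cohort simulator with
    closed-form expected MR estimates -- so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
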