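Package: secepr
Title: Secretome-Correlated Expression Patterns and Prognostic
    Gene-Combination Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates label-free quantitative (LFQ) secretome profiling
    of breast-cancer cell lines with PAM50-annotated patient expression
    cohorts. Calls proteins with subtype-specific secretion from LFQ
    intensity matrices (row z-scoring, reference-profile pattern matching,
    one-way ANOVA validation, Ward clustering), classifies
    secretion-correlated mRNA expression pattern (SeCEP) genes by
    Mann-Whitney tests with Benjamini-Hochberg adjustment over the full
    gene family, and exhaustively screens co-overexpression combinations
    of up to five SeCEP genes for dual-cohort prognostic significance
    using built-in Kaplan-Meier, log-rank and Cox proportional-hazards
    routines. A seeded synthetic-data generator emulates the cell-line and
    patient data shapes so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    withr,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
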