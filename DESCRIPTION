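Package: icrlung
Title: Immune-Constant-of-Rejection Classification and Benefit Association
    for NSCLC Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies non-small cell lung cancer tumors into four immune
    activation classes (ICR1-ICR4) from a 20-gene cytotoxic-immune panel by
    resampling-based consensus clustering, scores companion immune signatures
    (cell-subset metagenes, pathway activation, cytolytic activity, antigen
    presentation, T-cell-inflamed and tertiary-lymphoid-structure signatures),
    and tests association of class membership with durable clinical benefit
    after anti-PD1/PDL1 therapy (odds ratios, exact tests, logistic models,
    cross-cohort homogeneity) and with disease-free survival (Kaplan-Meier,
    log-rank). Includes nCounter-style count normalization, per-cohort
    quantile normalization and pooling utilities, and a multi-cohort
    synthetic data generator so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
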