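Package: ctorigin
Title: Tissue-of-Origin Classification from RT-PCR Gene-Panel Ct Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for molecular tissue-of-origin diagnosis of
    liver tumors from multi-gene RT-PCR expression panels. Covers two-stage
    specimen quality control with full sample accounting, multi-reference-gene
    delta-Ct normalization, SVM-RFE marker-panel selection, one-vs-rest linear
    hyperplane classification with Platt-scaled similarity scores that sum to
    100, and an evaluation suite (concordance tables, exact binomial confidence
    intervals, subgroup tests, micro-averaged multiclass ROC/AUC, average-linkage
    correlation clustering, discordance reports). Includes a synthetic-cohort
    generator that emulates panel RT-PCR data with tumor-purity contamination,
    differentiation-dependent signal attenuation, and quality-control failures,
    so the whole pipeline is testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    withr
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
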