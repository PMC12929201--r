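Package: pharmgap
Title: Pharmacotherapy Knowledge-Gap Landscapes and Pharmacovigilance Screens
    for Maternal and Pediatric Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify pharmacology publication evidence per drug by
    study type (pharmacokinetic, pharmaco-epidemiology, clinical trial) and
    patient subpopulation, classify knowledge gaps against claims-derived
    prescription rates, and screen high-use, low-evidence drugs for adverse
    event signals. Includes lexicon-based abstract annotation, cross-validated
    study-type triage with label calibration, four disproportionality
    statistics with lower credibility bounds (PRR, ROR, Bayesian information
    component, and the DuMouchel empirical-Bayes geometric mean), a nested
    case-control chi-square screen over claims-style cohorts, and seeded
    synthetic-data generators with recoverable ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
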