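Package: vitdpredict
Title: Predicted 25-Hydroxyvitamin D Exposure Modelling for Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and using a questionnaire-based prediction
    score for circulating 25-hydroxyvitamin D (25(OH)D) in prospective
    cohort studies. Implements repeated k-fold cross-validation with
    per-fold stepwise selection by Akaike's information criterion to derive
    and evaluate the prediction model; a time-updated exposure engine that
    carries forward missing covariates, computes per-cycle predicted scores
    and cumulative averages, and assigns exposure quartiles; and
    age- and period-stratified proportional-hazards analysis of incidence
    rate ratios across quartiles, with trend, subtype, subgroup and
    interaction analyses on counting-process person-period data. A
    calibrated synthetic-cohort generator reproduces the statistical
    structure of a biennial questionnaire cohort with a measured-biomarker
    sub-panel, so the full pipeline is testable without access to any
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
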