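Package: premor
Title: PreMO Childhood Myopia Risk Scores and External-Validation Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the age-banded PreMO (Predicting Myopia Onset and
    progression) risk indicator for non-myopic children from cycloplegic
    spherical equivalent refraction, axial length and parental myopia, and
    provides the external-validation pipeline used to evaluate it: ROC
    curve analysis with trapezoidal AUC, Youden-J optimal cut-off,
    sensitivity/specificity/false-positive rate, stratified bootstrap AUC
    confidence intervals, Spearman rank correlation with outcome
    refraction, and comparison against singular predictors. Includes a
    synthetic cohort generator with calibrated UK-like and Hong-Kong-like
    presets and exact fixture cohorts reconstructed from published
    contingency counts, so the whole pipeline is testable without access
    to the original clinical datasets.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
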