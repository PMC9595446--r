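Package: mldprep
Title: Machine-Learning-Driven Data Preparation for Tabular Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("mldprep", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolutionary search over restriction-constrained pipelines of
    data-preparation operators (outlier removal, feature selection,
    dimensionality reduction, resampling) for small tabular binary-endpoint
    cohorts such as radiomic feature tables. Selects and tunes an ordered
    preparation pipeline using training data only, with a ROC-distance
    fitness, and ships the full evaluation harness: Monte-Carlo
    cross-validation, dual-center independent validation, five fixed-default
    classifier schemes, confusion-matrix analytics with ANOVA and confidence
    intervals, cohort outlier/borderline diagnostics, and a ground-truth
    synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
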