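Package: mortclock
Title: Digital Short-Term Mortality Clocks from Longitudinal Registry Data
Version: 0.1.0
Authors@R:
    person("FinSim", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and auditing one-year mortality risk models
    ("digital aging clocks") on person-level administrative registry data:
    a synthetic-registry simulator with planted hazard signal and planted
    observation bias, prospective temporally-shifted cohort construction,
    age-year sequence encoding of longitudinal coded records, a gated
    recurrent risk model with an age+sex logistic baseline and penalized
    logistic / boosted-tree comparators, survival-aware evaluation (AUC,
    AUPRC, bootstrap confidence intervals, permutation tests, calibration,
    C-index, time-dependent AUC, Kaplan-Meier risk groups), an algorithmic
    fairness audit (group identification vs differentiation, equal-case
    binning, geometric-mean thresholds, age-sex matching, intersectional
    disadvantage reports) and Shapley explainability over longitudinal codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
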