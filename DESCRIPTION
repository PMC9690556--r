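Package: morbench
Title: Benchmarking Marginal Odds-Ratio Estimators Under Misspecification
    and Missing Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing estimators of the marginal treatment
    effect (marginal odds ratio) for a binary outcome in observational
    cohorts: covariate-adjusted logistic regression, propensity-score
    adjustment, 1:1 caliper matching, inverse-probability-of-treatment
    weighting, and targeted maximum likelihood estimation (TMLE) with a
    cross-validated super learner and inverse-probability weighting for
    missing outcomes.  Includes a structural (DAG-based) cohort simulator
    with counterfactual outcomes, MNAR/MAR/MCAR outcome amputation at
    controlled rates, and a Monte-Carlo harness that reports bias,
    empirical standard error and nominal coverage per estimator.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mgcv,
    pracma,
    purrr,
    ranger,
    Rcpp,
    rlang,
    rpart,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
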