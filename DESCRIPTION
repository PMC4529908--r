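Package: farms
Title: Forward and All-Subsets Regression for Model Selection
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variable selection for linear regression on wide datasets by
    iterating forward-style injection of fixed-size groups of candidate
    variables with an exhaustive best-subset search inside the bounded
    candidate pool, under Mallows' Cp, AIC, BIC, R-squared, adjusted
    R-squared or RSS.  Includes the classical baselines (forward selection,
    forward/backward stepwise, all-subsets regression), preprocessing for
    binary carriage covariates such as HLA alleles and peptide-response
    indicators, a univariate t-test screen with false-discovery-rate
    q-values, a robustness grid over the algorithm's two tuning parameters,
    and a synthetic-cohort generator for testing against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
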