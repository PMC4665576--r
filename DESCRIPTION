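Package: pvtrial
Title: Predictive Values for Risk Groups in Factorial Diagnostic Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation, interval estimation and comparison of positive and
    negative predictive values of diagnostic tests evaluated on the same
    subjects, stratified by risk groups whose prevalence is estimated from
    prior studies. Predictive values are obtained from sensitivity,
    specificity and prevalence via Bayes' theorem; their joint covariance
    across modalities is derived by the multivariate delta method, treating
    the prevalence as an estimated (not fixed) quantity. Provides additive
    and logit-scale confidence intervals with normal or t approximations,
    an ANOVA-type statistic for testing equality of predictive values
    across modalities or reader-by-method cells, generators for correlated
    multi-modality trial data, and a vectorised coverage-probability
    simulation engine for benchmarking the interval methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
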