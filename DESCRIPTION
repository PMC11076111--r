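Package: ismreg
Title: Measurement-Error-Corrected Estimation of the Effect of Higher
    Education on Intelligence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the effect of years of higher education on adult
    intelligence from pretest-posttest cohort data while correcting for two
    measurement problems that bias the usual covariate-adjusted regression:
    limited test-retest reliability of the childhood intelligence score, and
    non-classical error introduced when the adult score comes from a coarse,
    left-skewed discrete test. Provides the covariate (cov) and
    errors-in-variables (eiv) closed-form estimators and an iterated
    simulations (ism) fixed-point estimator that simulates latent
    start-of-education IQ consistent with the observed data and corrects the
    eiv moment equations for the dependence between discretization error and
    the predictors. Includes a calibrated synthetic-cohort generator,
    rank-based discretization schemes, selection-into-education simulators,
    nonparametric bootstrap inference, per-level model-fit diagnostics, and
    reproducible simulation-study runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
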