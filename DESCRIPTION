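Package: lcprofile
Title: Latent Class Profile Models with Time-Dependent Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent class profile models (LCPM) for multivariate
    categorical longitudinal data. The model places a categorical latent
    class variable at every time point and summarizes whole class
    trajectories into a second-layer latent profile variable. Profile
    prevalences are multinomial-logistic functions of baseline covariates
    and class memberships given a profile are multinomial-logistic
    functions of time-dependent covariates. Estimation is by maximum
    likelihood through a recursive forward-backward EM algorithm with
    Newton-Raphson updates for the regression coefficients, handling item
    nonresponse under a missing-at-random assumption. The package provides
    asymptotic standard errors from the observed information matrix, local
    identifiability diagnostics, BIC model-selection grids, a parametric
    bootstrap goodness-of-fit test, a likelihood-ratio test of
    time-invariant measurement, synthetic panel generation, and drivers for
    parameter-recovery and classification-accuracy simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    pracma,
    nnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
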