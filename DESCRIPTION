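Package: graftjlcm
Title: Joint Latent Class Modelling of Serum Creatinine Trajectories and
    Kidney Graft Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint latent class mixed models for long-term kidney transplant
    outcomes: a multinomial class-membership submodel, class-specific latent
    serum-creatinine trajectories observed through a monotone link function
    (linear, rescaled beta CDF, or quadratic I-splines), and class-specific
    Weibull proportional-hazards submodels for time to graft failure with
    right censoring and delayed entry. Includes model selection by BIC and
    the discretized AIC for comparing link families, individualized dynamic
    prediction of graft-failure risk with Monte-Carlo confidence bands,
    re-prediction after onset of de novo donor-specific antibodies or acute
    rejection, a confidence-interval based at-risk decision rule with
    confusion metrics, Kaplan-Meier and log-rank class comparisons, and a
    seeded synthetic cohort generator emulating scheduled creatinine visits
    and administrative censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    Rcpp,
    rlang,
    splines,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    lme4,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
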