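Package: erksense
Title: Stochastic Modelling and Mutual-Information Analysis of ERK Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify information transfer through a kinase
    signalling pathway from single-cell snapshot data. Implements an exact
    Gillespie (direct method) simulator for a stochastic ERK activation model
    with constitutive leak activation and two negative feedback loops (fast
    sequestration of the upstream effector by active ERK and slow, expression-
    dependent induction of a phosphatase), a binned plug-in mutual-information
    estimator with jackknife-style finite-sample bias correction and bootstrap
    uncertainty, a synthetic single-cell imaging data generator with dose-
    response, kinetic-profile and log-normal heterogeneity structure, and
    orchestration of feedback-strength sweeps, perturbation analogues and
    per-time-point mutual-information time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    pracma,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
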