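Package: csfields
Title: Spatio-Temporal Gaussian Random Field Modelling of Caesarean Section Rates
Version: 0.1.0
Authors@R:
    person("Registry", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Small-area estimation of annual Caesarean-section (CS) rates from
    individual birth records using a logistic regression model with a separable
    spatio-temporal latent Gaussian field: an isotropic Matern field (smoothness
    one) represented as a Gaussian Markov random field through the stochastic
    partial differential equation (SPDE) finite-element construction, combined
    with a stationary first-order autoregressive process across years.
    Hyperparameters and fixed effects are estimated by maximum likelihood with a
    Laplace approximation of the marginal likelihood; latent fields are reported
    as empirical Bayes modes. Includes a registry-style birth-record simulator
    with known ground truth, WHO Robson ten-group classification, cohort
    exclusion filters with flowchart-style accounting, and reporting utilities
    (parameter and odds-ratio tables, rate surfaces, GeoJSON export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
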