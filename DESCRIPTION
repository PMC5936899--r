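Package: vegclim
Title: Deterministic and Stochastic Dynamics of a Conceptual
    Climate-Vegetation Feedback Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for a zero-dimensional
    energy-balance climate model coupled to logistic vegetation dynamics.
    Provides the deterministic vector field with ice-albedo and
    vegetation-albedo feedbacks, equilibrium finding and stability
    classification, Andronov-Hopf scans over the vegetation death rate,
    separatrix and basin-of-attraction computation, Euler-Maruyama
    integration of the stochastic system with multiplicative noise on the
    vegetation growth rate, and noise-induced transition statistics
    (first-passage times, transition-probability sweeps over noise
    intensity, stationary temperature densities).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
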