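Package: isicorr
Title: Interspike-Interval Correlations in Adapting Neurons with Colored Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weak-noise theory and stochastic simulation of serial
    interspike-interval (ISI) correlations for multidimensional
    integrate-and-fire neurons with spike-triggered adaptation driven by a
    combination of white and colored (Ornstein-Uhlenbeck or green) noise.
    Provides deterministic limit-cycle solvers for the leaky, quadratic
    (theta) and generalized integrate-and-fire models, phase-response curves
    by closed form, adjoint integration and direct perturbation, closed-form
    serial correlation coefficients expressed as a sum of two geometric
    sequences, the coefficient of variation and the low-frequency spike-train
    spectrum, Euler-Maruyama simulators with ISI statistics estimators, a
    linearized stochastic-map Monte-Carlo oracle, and a Traub-Miles
    conductance-based model with an M-type adaptation current mapped into the
    same theory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
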