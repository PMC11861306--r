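Package: ccrfatigue
Title: Four-Compartment Controller Modelling of Localized Muscle Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, data processing and parameter estimation for a
    four-compartment controller model of localized muscle fatigue (4CCr) in
    which motor units move between resting, active, centrally fatigued and
    peripherally fatigued pools, with joint angular velocity governing the
    split between central and peripheral fatigue. Includes piecewise-constant
    task-profile construction for intermittent isometric and isokinetic
    protocols, a fixed-step compiled integrator with a three-compartment
    reference model, a processing pipeline for peak isometric torque data from
    dynamometer sessions (per-phase normalization, combinatorial least-squares
    scale fitting, fatigue-rate and velocity-regression summaries), a
    synthetic-session generator with known ground truth, and seeded global
    estimation of the velocity-dependent model parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
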