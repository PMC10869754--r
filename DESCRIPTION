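Package: vsdga
Title: Short-Trajectory Transition-Path Analysis of Voltage-Sensor Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates long-time kinetic statistics of conformational
    transitions from ensembles of short trajectories using the dynamical
    Galerkin approximation (DGA): forward committors, equilibrium reweighting
    factors, and mean first-passage times, together with the transition-path
    theory observables built from them (potentials of mean force with
    voltage tilts, reactive currents projected onto collective variables,
    committor-conditioned distributions, equilibrium time-correlation
    functions, and the sensing charge of a voltage-sensing domain).
    Includes structural collective variables for voltage-sensor analysis
    (helix translocation and rotation, displacement charge, salt-bridge
    distances, hydrogen bonds), sparse interpretable committor models via
    L1-penalized regression on inverse-sigmoid-transformed committors, and
    lag-integrated variational (IVAC) dimensionality reduction. Ships
    synthetic dynamics (discrete Markov chains, overdamped Langevin
    integrators, a five-basin voltage-sensor surrogate) with exact
    linear-algebra oracles for committors, stationary distributions,
    first-passage times, and reactive fluxes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    minpack.lm,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
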