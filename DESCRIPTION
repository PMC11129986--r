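Package: omzdyn
Title: Slow-Fast Plankton-Oxygen Dynamics and Oxygen Minimum Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for a three-component ocean model coupling
    dissolved oxygen, phytoplankton and zooplankton, with nonlinear
    (density-dependent) zooplankton mortality and an explicit timescale
    separation between the fast oxygen-phytoplankton dynamics and the slow
    zooplankton response. Provides steady-state location and Routh-Hurwitz
    classification, Hopf bifurcation thresholds with first Lyapunov
    coefficient, critical-manifold and fold-point computations for the
    slow-fast decomposition, Turing (diffusion-driven) instability analysis
    with the critical wavenumber, simulation-based detection of extinction
    thresholds, and an explicit finite-difference simulator for the 1-D
    reaction-diffusion system that reproduces oxygen-minimum-zone formation
    and global-anoxia regime shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
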