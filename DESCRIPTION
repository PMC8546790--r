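Package: tidelay
Title: Delay-Induced Dynamics in a Tumor-Immune Interaction Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and bifurcation analysis of a three-component delay
    differential equation model of tumor-immune interaction, in which mature
    T lymphocytes kill tumor cells and are recruited through a saturating
    stimulation term acting after a discrete time lag. The package locates
    and classifies equilibria, applies the Routh-Hurwitz criterion to the
    undelayed co-axial equilibrium, computes delay-induced crossing
    frequencies, critical delays and transversality from the characteristic
    quasi-polynomial, estimates the stability-preserving delay length,
    evaluates the center-manifold normal form of the Hopf bifurcation
    (first Lyapunov quantity, direction, cycle stability, period trend),
    integrates the model by a method-of-steps Runge-Kutta scheme with exact
    breakpoint alignment, and maps oscillatory regimes over one- and
    two-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
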