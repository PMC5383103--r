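Package: sphvalve
Title: Discrete Multi-Physics Simulation of Flow Through a Flexible Bicuspid Valve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional weakly-compressible smoothed particle
    hydrodynamics (WCSPH) solver coupled to a mass-spring-hinge membrane
    model for simulating pulsatile blood flow through a flexible bicuspid
    valve. Includes an on-line liquid-to-solid phase-change algorithm that
    grows and fragments solid aggregates (calcification and clot analogues)
    inside the flow, scene builders with analytic validation fixtures
    (Poiseuille, Womersley, cantilever), dimensionless-group analysis of
    membrane deformation regimes, and field reconstruction / snapshot output
    (CSV and legacy VTK).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
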