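Package: poroTME
Title: Poroelastic Reaction-Diffusion-Advection Modelling of the Tumor
    Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of an osteosarcoma tumor microenvironment as
    a bio-mechanical multiphase continuum. A 14-species
    reaction-diffusion-advection system for immune cells, cancer cells and
    cytokines is coupled to quasi-static Biot poroelasticity on a
    two-dimensional disk: the cell populations that make up the solid tumor
    generate an eigenstress that deforms the porous skeleton, and the Darcy
    flow of interstitial fluid can advect motile species. The package
    provides a structured triangular finite-element kernel (quadratic
    displacements, linear pressure, rigid-body Lagrange constraints), a
    calibrated synthetic generator for the immune interaction network, the
    spatially uniform reference reduction, tumor-size estimation from the
    displacement field, and scenario simulations for boundary immune influx
    and localized cell sources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
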