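Package: porolung
Title: Poroelastic Flow-Structure Simulation of Airflow-Driven Lung Deformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Finite-element simulator of breathing-induced deformation of a
    multizone poroelastic lung phantom. The parenchyma is treated as a porous
    elastic medium: a Richards-type pore-pressure equation (storage, Darcy
    flux, skeleton dilatation) is coupled to a quasi-static poroelastic Navier
    equation with optionally orthotropic, spatially varying shear moduli.
    Includes a graded multizone tetrahedral phantom generator, synthetic
    anisotropic Young's-modulus field generation with prescribed statistics
    (range and volume-weighted mean), a staggered implicit flow-structure
    coupling scheme, and breathing-cycle kinematics analysis: landmark
    displacement traces, hysteresis peak-lag times, cycle-stability index,
    trajectory loop closure, and target deformation error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
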