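Package: shearcyte
Title: Shear Flow Deformation Cytometry of Suspended Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of shear flow deformation cytometry experiments, in
    which suspended cells are pumped through a long square microchannel in a
    high-viscosity shear-thinning medium and imaged at the channel mid-plane.
    Computes the fluid shear stress field from the square-duct series
    solution, fits the Cross shear-thinning model to observed cell speeds,
    extracts each cell's storage modulus G' and loss modulus G'' from its
    steady-state elliptical shape and alignment angle via the theory of a
    viscoelastic sphere in viscous shear flow, measures tank-treading
    rotation by dense optical flow, and scales per-cell moduli to a 1 Hz
    power-law stiffness k and fluidity alpha with a 2-D kernel-density
    population mode. Includes a forward simulator that generates detection
    tables and rendered image stacks with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
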