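Package: hemofsi
Title: Pulsatile Arterial Hemodynamics with Fluid-Structure Interaction
    and a Porous Microcirculation Outlet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of pulsatile blood flow in a compliant
    straight artery terminated by a porous "seepage" zone standing in for
    the downstream microcirculation.  The flow is solved on an
    axisymmetric moving (arbitrary Lagrangian-Eulerian) staggered grid
    with Carreau-Yasuda shear-thinning rheology; the microcirculation is
    a Darcy-Brinkman porous continuum with Kozeny-Carman permeability;
    the arterial wall is an inertial linear-elastic ring model coupled to
    the fluid by a partitioned staggered scheme with Aitken relaxation.
    Includes analytic verification oracles (Poiseuille, Womersley,
    Darcy, Moens-Korteweg), probe/cycle post-processing, rigid-wall
    comparison runs and Young's-modulus sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
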