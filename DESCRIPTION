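Package: ionplan
Title: Pencil-Beam Scanning Ion Therapy Planning with Variable RBE
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale treatment-planning pipeline for comparing proton and
    helium-ion pencil-beam-scanning plans on synthetic meningioma-like
    phantoms. Provides analytic Bragg-curve and dose-averaged LET beam
    models, sparse voxel-by-spot influence matrices, linear-quadratic
    RBE-weighted dose with fixed (1.1) and variable LET-dependent RBE,
    two-stage spot-weight optimization under DVH-style constraints, and DVH
    parameter extraction with inter-plan difference tables, dose-level masks
    and dose-difference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
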