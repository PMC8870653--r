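Package: holomass
Title: Virtual Off-Axis Holographic Microscopy and Cell Dry-Mass Cytotoxicity Assays
Version: 0.1.0
Authors@R: person("Holomass", "Developers", email = "holomass@example.org",
    role = c("aut", "cre"))
Description: A simulate-reconstruct-quantify toolkit for label-free
    cytotoxicity assays based on quantitative phase imaging (QPI) with
    off-axis digital holographic microscopy (DHM). Synthetic cell
    populations are rendered as phase objects with known analytic dry
    mass, imaged through an off-axis hologram forward model (carrier
    fringes, spherical aberration, defocus, coherent and detector noise),
    reconstructed by spectral sideband filtering with aberration
    compensation, numerical refocusing, phase unwrapping and multi-frame
    averaging, background-corrected by a rolling-ball estimator, and
    scored by field-of-view dry-mass time courses, 24-h dry-mass
    increments, and two-sided t-tests with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
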