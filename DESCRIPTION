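Package: headblast
Title: Desk-Scale Blast Loading Simulation of a Gyrified Head Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-dimensional (plane strain) explicit-dynamics simulation of
    blast overpressure loading on a parametric gyrified head phantom.
    Generates a conformal quadrilateral mid-plane mesh with skull, CSF layer,
    gray and white matter, gyri and sulci, ventricles and optional embedded
    vascular channels; loads the skull exterior with a Friedlander blast
    waveform including Rankine-Hugoniot reflection amplification and a
    sweeping arrival front; advances a Lagrangian central-difference solver
    with a Tillotson-Brundage volumetric equation of state, pressure-cutoff
    cavitation, Prony-series viscoelastic shear for brain tissue and elastic
    skull; and reports interface strain, strain-rate and cavitation
    co-localization metrics by anatomical region and vessel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
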