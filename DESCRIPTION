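Package: rtclear
Title: CT-Based Gantry-Couch Collision Prediction for Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts mechanical collisions between the linac gantry, the
    treatment couch, and the patient (or immobilization accessories) for
    coplanar and noncoplanar beam geometries, directly from a simulation CT
    series and a parametric machine description. Provides automatic external
    contouring of CT volumes, lofting of planar contours into watertight
    triangle meshes, rigid gantry/couch kinematics, margin-aware mesh
    proximity queries over configuration-space sweeps, minimal isocenter
    shift search to clear collisions, and a confusion-matrix validation
    harness against a fine in-silico oracle. Includes a synthetic CT phantom
    generator and two generic fixture machines so the full pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
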