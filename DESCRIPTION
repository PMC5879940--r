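Package: cupver
Title: Acetabular Cup Anteversion Measurement from Plain Radiographs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying plain-radiograph
    measurements of acetabular component anteversion after total hip
    arthroplasty. Projects a hemispherical cup and prosthetic head onto
    anteroposterior and cross-table lateral films (parallel or point-source
    beam), extracts the landmarks required by six published measurement
    methods (Liaw, Lewinnek, Widmer, Hassan, Ackland, Woo-Morrey),
    re-implements an edge-detection reference standard (circle fits plus a
    centre-constrained opening-ellipse reconstruction), generates synthetic
    observer-annotated cohorts with known ground truth, and computes
    reliability (two-way random-effects intraclass correlation with
    confidence intervals) and accuracy (paired differences against the
    reference) summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
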