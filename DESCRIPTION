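Package: sonomargin
Title: Ex Vivo 3D Ultrasound Resection Margin Assessment Against
    Histopathology
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for comparing intra-operative 3D ultrasound
    margin measurements of resected tongue squamous cell carcinoma specimens
    with postoperative histopathology. Provides label-volume and slide-stack
    containers with NRRD/NIfTI/PNG readers and writers, fiducial-based
    slide-to-ultrasound slice correspondence, 45-degree partitioning of the
    resection surface into cranial, deep and caudal regions, exact
    spacing-aware distance measurements (tumor thickness, per-region and
    anterior/posterior margins), Spearman and Bland-Altman agreement
    analysis with exclusion sensitivity, and a digital specimen phantom
    generator with analytic ground truth emulating fixation shrinkage and
    4 mm sectioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
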