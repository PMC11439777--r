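Package: phytosynth
Title: Synthetic Training Data Generation and Evaluation for Greenhouse
    Plant-Disease Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Procedurally generates labeled images of healthy and diseased
    tomato branches (parametric branch and compound-leaf geometry, layered
    leaf material synthesis with parametric disease alterations, simplified
    Lambertian scene rendering against a procedural greenhouse backdrop),
    builds balanced PNG+CSV training datasets, trains a compact
    convolutional binary classifier purely on the synthetic images under
    staged augmentation regimes, scores images with a test-time-augmentation
    ensemble and a threshold-corrected decision rule, and tracks the
    iterative development process with an explicit cost model and stopping
    rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    digest,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
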