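Package: rernet
Title: Blood-Cell Image Classification with an Ensemble of Randomized Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies white blood cell images (eosinophil, lymphocyte,
    monocyte) with a residual convolutional backbone used as a feature
    extractor feeding three randomized neural networks - a Schmidt neural
    network, an extreme learning machine, and a deep random vector
    functional link network - whose hidden weights are random and frozen
    and whose output weights are solved in closed form by Moore-Penrose
    pseudoinverse least squares. Predictions of the three members are
    fused by hard-label majority voting with a fixed fallback class.
    Includes stratified repeated k-fold cross-validation, one-vs-rest
    per-class and macro metrics with Student-t confidence intervals,
    Grad-CAM attention maps, and a synthetic blood-cell image and feature
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
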