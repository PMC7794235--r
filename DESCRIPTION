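Package: otoseg
Title: Automated Temporal-Bone CT Segmentation with HU-Constrained Refinement
Version: 0.1.0
Authors@R:
    person("Otoseg", "Developers", email = "otoseg@example.org",
           role = c("aut", "cre"))
Description: End-to-end automated segmentation of temporal-bone CT
    structures (inner ear, ossicles, facial nerve, sigmoid sinus) and
    derivation of the otic capsule. Provides NIfTI-backed volume and label
    containers with geometric resampling, intensity preprocessing, a small
    trainable 3D encoder-decoder segmentation network with Dice-based
    training and k-fold cross-validation, Hounsfield-unit-constrained
    morphological refinement of predicted masks, an objective evaluation
    suite (Dice coefficient, average Hausdorff distance, volumetric
    similarity), and a procedural temporal-bone CT phantom generator used
    as the test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
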