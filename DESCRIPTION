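Package: stemCT
Title: Stem Cross-Section Micro-CT Phenomics for Vascular Bundle Traits and
    Bending-Strength Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for microanatomical phenotyping of plant stem cross-sections
    from micro-CT image stacks. Simulates CT-like cross-section images with
    exact ground truth, segments the stem into epidermis/periphery/inner zones,
    detects vascular bundles with a marker-controlled watershed, and computes
    32 microanatomical traits including engineering-mechanics descriptors
    (moment of area, polar moment of inertia and its axial decomposition).
    Converts three-point-bending load-displacement curves into bending moments,
    fits multi-environment random-effects models for variance components,
    BLUPs and broad-sense heritability, and evaluates trait-based prediction
    of stem bending strength with recursive feature elimination and
    cross-validated regression models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    ranger,
    e1071,
    nnet,
    rpart,
    glmnet,
    jsonlite,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
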