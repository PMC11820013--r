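Package: camil
Title: Cascaded Spatial-Channel Attention Multiple Instance Learning for
    Whole-Slide Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weakly supervised classification of whole-slide pathology
    images by multiple instance learning (MIL). Each slide is a bag of
    patch feature vectors carrying only a slide-level binary label. The
    core model refines the bag's instance features with a cascaded
    attention block - an N x N spatial (instance-to-instance) attention
    stage followed by a C x C channel attention stage, each entering
    through a zero-initialized residual gate - then aggregates instances
    by attention pooling into a bag embedding scored by a sigmoid head.
    Includes slide tiling with saturation/Otsu tissue filtering, a
    pluggable patch encoder, a flat-file feature store, full training
    (Adam, cosine annealing, early stopping, one bag per batch),
    stratified k-fold cross-validation with the standard metric suite,
    gradient-based instance attribution with heatmap reprojection, and a
    seeded synthetic bag/slide generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
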