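Package: xcelunet
Title: Dual-Task Volumetric Shoulder CT Segmentation and Glenohumeral Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-aware dual-decoder 3D convolutional network for simultaneous
    segmentation of the proximal humerus and scapula in shoulder CT and staging
    of three glenohumeral clinical conditions (osteophyte size, joint-space
    narrowing, humeroscapular alignment). Provides the region/contour losses
    with a scheduled Dice weight, inverse-frequency class balancing, four
    transfer/fine-tuning regimes over the segmentation backbone, gradient-based
    3D class activation maps, marching-tetrahedra surface reconstruction with
    one-way RMSE/Hausdorff mesh metrics, and a seeded synthetic shoulder
    phantom generator with known segmentation and condition ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
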