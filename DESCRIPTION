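Package: thermocloud
Title: LiDAR-Thermal Camera Fusion for 3D Fruit Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds 3D thermal point clouds from a mobile 2D LiDAR line
    scanner and a radiometric thermal camera, and segments per-fruit
    surface temperature from apple-tree scans. Implements intrinsic
    thermal-camera calibration from an actively heated lightbulb board
    (staged multi-threshold blob detection, planar bundle refinement),
    extrinsic LiDAR-to-camera calibration (RANSAC plane location, PCA
    initial pose, ICP refinement, reprojection-minimising pose solve,
    cross-scan model selection), projection-based temperature fusion with
    an out-of-view sentinel, eigenvalue-curvature plus reflectance fruit
    segmentation, ground-truth scene simulators for every pipeline stage,
    and the evaluation metrics (RMSE, MBE, adjusted R-squared, detection
    F1) used to assess them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
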