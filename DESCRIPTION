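Package: plantfuse
Title: Non-Rigid 3D Reconstruction of Plants from Depth Video with Sensor Data Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Turns short sequences of depth frames of a moving (non-rigid)
    plant into a single fused triangulated 3D surface model, and fuses
    height-indexed environmental sensor readings (temperature, humidity,
    luminosity) into that model by gradient colorization. Implements a
    logarithmic depth-threshold background filter, octree standardization,
    statistical outlier removal, bilateral point-cloud smoothing,
    advancing-front surface reconstruction, deformation graphs with SHOT
    keypoint description and bidirectional matching, SR-ARAP non-rigid mesh
    deformation, and weighted-average TSDF volume fusion with marching-cubes
    extraction. Includes a synthetic depth-scene generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
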