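Package: tasselseg
Title: Branch Segmentation and Morphological Trait Extraction for Maize
    Tassel Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for organ-level analysis of 3-D maize tassel point
    clouds. Implements the full pipeline from a raw colored point cloud to
    six morphological traits: HSV foreground masking, statistical outlier
    removal and farthest-point downsampling; a hierarchical point-set
    (PointNet++-style) encoder-decoder that labels branch-tip points, with
    a native training loop; density-based clustering of tip points into
    branch instances; bottom-up minimum-path skeleton extraction over a
    radius graph; and per-branch trait computation (count, length,
    insertion angle, curvature, convex-hull volume, dispersion). A
    parametric synthetic-tassel generator with analytic ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
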