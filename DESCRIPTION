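Package: phenopoint
Title: Point-Cloud Phenotyping of Greenhouse Tomato Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for organ-level analysis of colored 3D point clouds of
    greenhouse tomato seedlings. Provides PLY input/output, region-of-interest
    condition filtering, a 16-variant rotation/mirror augmentation scheme,
    K-means color denoising and Excess Green Index vegetation segmentation,
    voxel-grid and farthest-point downsampling with hardware-independent cost
    counters, a compact hierarchical point-set segmentation network whose
    set-abstraction sampling layer uses voxel-grid downsampling, geometric
    trait extraction (leaf length by space-curve fitting, stem diameter by
    oriented-bounding-box alignment and least-squares circle fitting),
    support-weighted segmentation metrics, and a deterministic synthetic plant
    generator with known ground-truth traits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
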