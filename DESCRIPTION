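Package: shootseg
Title: Leaf/Stem Segmentation Baselines for 3D Plant Shoot Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical baselines for semantic segmentation of 3D plant shoot
    models into leaf and stem, as used for X-ray CT rosebush data: an
    unsupervised Markov-random-field graph-cut labeling of point clouds driven
    by covariance eigenvalue curvature, a multi-scale eigen-feature linear
    support vector machine, and a volumetric Gaussian filter-bank random
    forest voxel classifier. Includes point-cloud (PLY/XYZ) and voxel-volume
    (multi-page TIFF) input/output, surface-voxel extraction, a seeded
    synthetic labeled plant-phantom generator (tube stems and petioles, thin
    curved leaflets), and the per-class precision/recall/IoU evaluation
    protocol with flower-class exclusion.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
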