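Package: myomatrix
Title: Quantitative Analysis of Myofibrillar Matrix Connectivity in 3D Muscle Volumes
Version: 0.1.0
Authors@R: person("Muscle", "Imaging", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the branching network of sarcomeres (the myofibrillar
    matrix) from labeled 3D muscle image volumes such as those produced by
    FIB-SEM segmentation. Provides volume input/output with voxel metadata
    (multi-page TIFF and HDF5), a ground-truthed synthetic muscle volume
    generator spanning fibrillar (unbranched) through highly branched tubular
    regimes, longitudinal segment-graph construction with split/merge junction
    detection and single/multi classification, myofibril tracking with
    field-of-view censoring, per-slice morphometry (cross-sectional area,
    circularity), volume-weighted summaries, distance-transform based
    peripheral-bias analysis, and hierarchical per-cell ("SuperPlot")
    statistics with a variance-gated post hoc decision tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    yaml,
    matrixStats,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
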