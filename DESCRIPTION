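Package: sparclet
Title: Dose-Averaged LET Optimized Treatment Planning for Spot-Scanning Proton Arc Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale inverse treatment-planning toolkit for spot-scanning
    proton arc therapy (SPArc) and multi-beam intensity-modulated proton
    therapy (IMPT) that optimizes dose-averaged linear energy transfer (LET_d)
    jointly with dose. Provides synthetic voxel phantoms, an analytical proton
    pencil-beam engine (Bragg depth-dose and depth-LET_d curves, exact
    voxel-traversal water-equivalent path length), sparse spot-to-voxel dose
    and LET influence matrices, a quadratic dose+LET_d objective with exact
    gradients and bound-constrained optimization, coarse-to-fine arc
    control-point sequencing with energy-layer redistribution and reduction,
    deliverable minimum-MU post-processing, delivery-time simulation, and
    DVH/LVH plan evaluation with reproducible comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
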