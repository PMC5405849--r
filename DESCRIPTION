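Package: surseg
Title: Super-Region Segmentation of 3D Biological Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable workbench for semi-automatic segmentation of low
    signal-to-noise 3D biological volumes (cryo soft X-ray tomography,
    cryo electron tomography, FIB-SEM). Volumes are over-segmented into a
    three-layer super-region hierarchy (voxels, SLIC supervoxels,
    agglomerated megavoxels), described with denoising and textural
    feature channels, classified from sparse user annotations with tree
    ensembles, and spatially refined with a boundary-weighted Potts
    Markov random field solved by alpha-expansion graph cuts. Includes
    hierarchical label constraints, morphological post-processing,
    per-object morphometry with rule-based label splitting, MRC and HDF5
    volume I/O, and a synthetic phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    ranger,
    igraph,
    yaml,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    xgboost,
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
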