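Package: nodecad
Title: Two-Stage Lymph Node Detection for MR Lymphography with
    Multi-View Convolutional False-Positive Reduction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A computer-aided detection (CAD) pipeline for lymph nodes in
    dual-channel 3D pelvic MR Lymphography volumes. Stage one computes
    per-voxel intensity, Hessian-based shape (blobness, vesselness,
    sheetness) and positional features, classifies voxels with a
    GentleBoost ensemble of regression stumps, and extracts candidate
    locations by spherical-window local maxima detection with plateau
    merging. Stage two rescores each candidate with a multi-view (1-, 3-
    or 9-view) convolutional neural network that samples 2D patches on
    the symmetry planes of a cube enclosing the candidate. Evaluation
    provides FROC analysis with patient-level bootstrap confidence
    bands, partial AUC, one-sided bootstrap system comparison with
    Bonferroni correction, and stratified patient-level cross-validation.
    A synthetic phantom generator emulating 0.8 mm isotropic dual-channel
    acquisitions with nodular, tubular and sheet-like structures makes
    the whole pipeline trainable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, ImageAnalysis, Classification
RoxygenNote: 7.3.3
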