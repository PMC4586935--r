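Package: framelight
Title: Reference-Frame Evidence Combination for Multivoxel Pattern Analysis
Version: 0.1.0
Authors@R: person("Framelight", "Developers", role = c("aut", "cre"),
    email = "framelight@example.org")
Description: Tools for deciding whether multivoxel fMRI activity patterns
    encode movement targets in gaze-centered or body-centered coordinates.
    Implements the full two-sided evidence pipeline: per-run GLM t-patterns,
    leave-one-run-out linear SVM classification (distinct-pattern evidence),
    replacement-routed cross-classification (common-pattern evidence),
    conjunction and aggregation of the two evidence streams per reference
    frame, a gaze-direction control test, voxel-averaged searchlight mapping,
    group-level GLM inference with cluster-extent thresholding, and
    local-maximum region-of-interest statistics. Ships a synthetic-data
    generator with known ground-truth coding schemes so every stage has a
    recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
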