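Package: engramtrack
Title: Ensemble Detection and Cross-Session Pattern Tracking for Calcium Imaging of Engram Cells
Version: 0.1.0
Authors@R:
    person("Engramtrack", "Developers", email = "engramtrack@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discriminating hippocampal engram from
    non-engram cells in head-mounted-microscope calcium imaging. Implements
    sliding-window correlation-matrix overlap statistics with Monte-Carlo
    shuffle controls, the restricted Mahalanobis population-vector distance,
    non-negative matrix factorization of population activity with AICc
    model-order selection and multi-restart optimization, cosine-similarity
    matching scores with shuffle nulls, cross-session pattern fate
    classification (aligned/isolated), and identification of
    reporter-expressing cells from fluorescence snapshots by thresholding and
    watershed segmentation. Ships a synthetic-experiment generator with
    planted sub-ensembles and full ground truth so every stage is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
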