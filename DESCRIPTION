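Package: actionrsa
Title: Representational Similarity Analysis for Condition-Rich Naturalistic
    Action Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the representational geometry of observed
    actions with condition-rich, rapid event-related designs. Generates
    serially balanced (type 1 index 1) trial sequences with jittered,
    efficiency-optimized timing; builds representational dissimilarity
    matrices (RDMs) from split-session neural response patterns, multiple
    arrangement behavioral tasks, gaze trajectories, word-embedding
    semantics, and precomputed feature spaces; relates model RDMs to neural
    RDMs by rank correlation and joint rank regression with hierarchical
    variance partitioning and intersubject noise ceilings; and performs
    group-level resampling inference (sign-flip permutation, re-centered
    bootstrap, condition-label permutation nulls, bootstrap confidence
    intervals over subjects and stimuli). A synthetic-data module simulates
    every pipeline input from known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
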