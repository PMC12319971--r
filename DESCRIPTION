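Package: substates
Title: Dynamic Brain-Activity Substates from Time-Resolved fMRI Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects temporal substates of whole-brain activity in paired
    pharmacological resting-state fMRI designs. Builds per-participant
    time-by-time spatial-similarity matrices from parcellated BOLD series,
    subtracts group-mean matrices across conditions, and identifies
    condition-specific substates by threshold-swept Louvain community
    detection with signed-modularity variants, selecting the operating
    threshold by a pre/post-injection separability criterion. Provides
    substate occupancy and chi-square statistics, indicator-design GLM
    beta-maps with paired FDR-controlled contrasts, continuous heart rate
    derived from EKG traces (rectification, zero-phase wavelet band
    enhancement, constrained R-peak detection, instantaneous 60/RR heart
    rate resampled onto the fMRI volume grid), SIMPLS partial least squares
    association between physiological change and subjective-experience
    change scores, and a synthetic paired-cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
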