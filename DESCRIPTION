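Package: wmstates
Title: Single-Trial On/Off State Analysis of Working-Memory Population Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the single-trial dynamics of mnemonic
    information in simultaneously recorded neural populations during spatial
    working-memory delays. Implements leave-one-trial-out logistic decoding of
    cue location with a time-resolved classifier-confidence output, shuffle-null
    cluster-mass segmentation of the delay into coding ('On') and
    non-coding ('Off') states, beta-mixture model comparison of confidence
    distributions by cross-validated bits per trial, state-conditioned tuning and
    population-rate analyses, jitter-corrected spike-train cross-correlograms
    with a condition-specific functional-connectivity graph comparison
    (Manhattan-distance permutation test), joint-selectivity enrichment, and
    control analyses (microsaccade detection, LFP phase-state association,
    background-noise estimation). Ships an inhomogeneous Bernoulli spike-train
    simulator with population-coordinated On/Off epochs, von Mises cue tuning and
    injected pairwise synchrony that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    arrow,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
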