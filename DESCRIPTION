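Package: wplinet
Title: Time-Resolved wPLI Connectivity and Network Permutation Statistics
    for Event-Related MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-resolved functional connectivity analysis of
    event-related source-space MEG recordings. Computes instantaneous phase
    via the analytic signal, weighted phase lag index (wPLI) connectivity
    matrices at every time sample, baseline z-score normalization, and
    whole-brain connectivity timeseries. Inference uses a supra-threshold
    cluster permutation test over time, the Network-Based Statistic (NBS)
    with family-wise error control by the maximal connected component, a
    masked network-sum permutation test for group contrasts, and
    brain-behaviour correlations. Includes a coupled-oscillator cohort
    simulator with planted band- and window-specific networks and full
    ground truth, plus trial screening by head motion and sensor amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
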