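Package: plvnet
Title: Source-Level Phase-Locking Networks for Go/NoGo EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Weighted functional brain-network analysis of event-related EEG:
    stimulus-locked epoching, amplitude-based artifact rejection, zero-phase
    band-pass filtering, regularized minimum-norm source estimation on a
    synthetic forward model, phase-locking-value (PLV) connectivity in the
    NoGo-P3 window, weighted graph indices (strength, Onnela clustering,
    characteristic path length, global efficiency) at global and nodal level,
    and covariate-adjusted group statistics with Bonferroni control, partial
    eta squared effect sizes and partial Pearson correlations. Includes a
    phase-coupled oscillator cohort simulator with analytic expected PLV so
    the whole chain is testable without recorded EEG.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
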