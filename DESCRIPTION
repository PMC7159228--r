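Package: dilisvm
Title: Ensemble SVM Prediction of Drug-Induced Liver Injury from
    Adverse-Event Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for building a compound-attribute
    classifier of drug-induced liver injury (DILI) from spontaneous
    adverse-event reports. Aggregates FAERS-style report tables into a
    drug-event count matrix, computes disproportionality statistics
    (relative reporting ratio with Fisher exact significance), derives
    rule-based positive and negative drug cohorts, and trains an ensemble
    of balanced-undersampling linear support vector machines with
    recursive feature elimination. Per-trial feature selections are
    aggregated into a frequency-ranked consensus set used to fit a final
    probability-thresholded model over molecular descriptor tables.
    Includes synthetic generators for report sets and descriptor matrices
    with planted ground truth.
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
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
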