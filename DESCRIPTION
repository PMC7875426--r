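Package: stabvar
Title: Stability-Selected Elastic-Net Vector Autoregression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed, lagged, directed gene regulatory networks from
    short replicated expression time series using Granger causality.  Each
    gene is regressed on the lagged expression of all genes under an elastic
    net penalty; a permutation null calibrates a per-gene, per-lag edge
    false discovery rate, and bootstrap stability selection with a second,
    independent permutation calibrates a network-wide selection-frequency
    cutoff.  Includes a sparse vector-autoregression simulator with planted
    edges, precision-recall and ROC benchmarking against gold-standard edge
    lists, gene-class enrichment statistics, and an unpenalized pairwise
    autoregression for validating inferred edges on perturbation series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
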