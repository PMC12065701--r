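Package: ghpat
Title: Goldner-Harary Graph-Pattern Feature Engineering for EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a self-organized feature-engineering pipeline for
    two-class EEG classification built around GHPat, a textural feature
    extractor that encodes each overlapping 11-sample signal block with one of
    seven directed subgraphs of the Goldner-Harary graph, chosen per block by
    a distance-based fitness function. The pipeline combines a seven-level
    symlet-4 discrete wavelet decomposition, 14 statistical moments, iterative
    neighborhood component analysis (INCA) feature selection, a weighted
    k-nearest-neighbour classifier with leave-one-subject-out
    cross-validation, iterative majority voting across channels, and greedy
    selection of the most accurate result. Includes a seeded generator of
    EEG-like two-class cohorts with subject structure and band-power class
    effects, plain-text and EDF record I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
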