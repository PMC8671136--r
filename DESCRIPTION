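Package: eiic
Title: Site-Robust Functional Connectivity Classification with Extended
    Invariant Information Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements extended invariant information clustering (EIIC), a
    labeled-pair contrastive learning method for classifying autism spectrum
    disorder from resting-state functional connectivity across heterogeneous
    acquisition sites. Provides Fisher-z connectivity feature extraction from
    ROI-averaged BOLD time series, the lambda-weighted mutual-information
    (IIC) loss with an overclustering head, a shared-trunk multi-head network
    trained in two phases (contrastive prior learning, then transfer learning
    with a frozen trunk), a full leave-one-site-out cross-validation harness
    with stratified five-fold inner validation and five-model ensembling, and
    a seeded multi-site synthetic data generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
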