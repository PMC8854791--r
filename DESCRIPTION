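Package: lparp
Title: Label Propagation and Similarity Projection for lncRNA-Disease
    Association Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage bipartite link prediction for long noncoding RNA
    (lncRNA)-disease association inference. Gaussian interaction-profile
    kernel similarities computed from a sparse binary association matrix
    are integrated with optional disease semantic similarity (Wang's
    directed-acyclic-graph method) and lncRNA functional similarity;
    label propagation on the normalized lncRNA and disease similarity
    networks yields estimated association scores, which are refined by a
    deterministic similarity-weighted projection with column
    normalization. Ships leave-one-out and entity-holdout
    cross-validation protocols with ROC/AUC evaluation, a planted-block
    synthetic data generator, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Network, Classification
RoxygenNote: 7.3.3
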