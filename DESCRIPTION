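Package: jsnmf
Title: Joint Symmetric Non-Negative Matrix Factorization for
    Multi-Subject Brain Network Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters collections of weighted undirected networks (one
    per subject, e.g. resting-state functional brain networks) into a
    shared set of modules by jointly factorizing every adjacency matrix
    as H S(v) H' with one common non-negative indicator matrix H and a
    per-subject compression matrix S(v), under an L1 sparsity penalty on
    H.  Provides the multiplicative-update optimizer with restarts and
    representative-run selection, weighted module-quality indices
    (modularity, conductance, coverage), module-restricted edge-weight
    feature extraction, leave-one-out classifier evaluation with ROC/AUC,
    recursive-feature-elimination and binary particle-swarm feature
    selection wrappers, and generators for synthetic multi-view networks
    with a planted module structure and labeled two-group cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    igraph,
    e1071,
    randomForest,
    glmnet,
    class,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
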