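Package: acnmf
Title: Automatic Consensus Non-Negative Matrix Factorization for
    Single-Cell Gene Expression Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers reproducible gene expression programs in single-cell
    RNA-seq count data by consensus non-negative matrix factorization with
    automatic selection of the factorization rank and of the "Jaccard
    length" used to compare programs. Programs recovered independently in
    two random halves of the data are matched by an exact hypergeometric
    test on their top-weighted gene sets, reaggregated by edge-betweenness
    community detection, and the rank is chosen at the inflection of the
    replicated-community curve. Includes a splatter-style count simulator
    with planted cell-type and activity programs, cross-dataset program
    graphs, marker-set enrichment scoring, and a copy-number-feature
    classifier for resolving ambiguous cancer/normal cell identities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    yaml,
    glmnet,
    randomForest,
    e1071,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
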