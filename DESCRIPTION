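Package: nmfsubtypes
Title: Molecular Subtyping of Bulk Expression Data by Consensus
    Non-Negative Matrix Factorization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers molecular subtypes in bulk gene-expression count data
    with divergence-based non-negative matrix factorization (Lee-Seung
    multiplicative updates), selects the number of subtypes by the cophenetic
    correlation of a consensus matrix built over repeated randomly
    initialized runs, filters core samples by silhouette width, defines
    per-subtype signature genes by differential expression, transfers
    subtypes to independent cohorts by signature projection and
    re-clustering, and tests subtype-covariate associations with exact
    contingency-table (Freeman-Halton) and t tests.  Includes a
    negative-binomial simulator with planted subtype structure so the whole
    pipeline is testable without external data, plus hypergeometric
    over-representation analysis for user-supplied GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    edgeR,
    fgsea,
    grDevices,
    graphics,
    jsonlite,
    Matrix,
    methods,
    pheatmap,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
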