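Package: netAlignFW
Title: Scalable Network Alignment via Stochastic Block-Coordinate Frank-Wolfe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Aligns and queries protein-protein interaction networks using the
    IsoRank eigenvector formulation solved as a simplex-constrained quadratic
    program. The maximal right eigenvector of the product-graph transition
    matrix is found by a generalized stochastic block-coordinate Frank-Wolfe
    algorithm whose per-iteration cost and memory stay far below the size of
    the quadratic product matrix, which is never materialized. Includes
    implicit Kronecker-product operators, closed-form block linear-minimization
    oracles, analytic step sizes, tracked-residual recurrences, greedy
    alignment extraction, and a synthetic planted-query benchmark suite with
    dense brute-force oracles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
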