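Package: circularnet
Title: Phylogenetic Split Networks from Distance Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes outer-labeled planar phylogenetic split networks from
    pairwise distance matrices using the agglomerative neighbor-net approach:
    a circular ordering of the taxa is obtained by iterative joining of
    chain components, non-negative split weights for the induced circular
    split system are estimated by constrained least squares using implicit
    O(n^2) operators for the circular design matrix (active-set with
    truncated conjugate gradients, gradient projection, and accelerated
    projected gradient solvers), and the resulting weighted split system is
    drawn as a planar split network or its boundary outline. Includes
    readers and writers for PHYLIP distance matrices and SplitsTree
    compatible Nexus files, a synthetic-data generator with known ground
    truth, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    igraph,
    phangorn,
    stats,
    graphics
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
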