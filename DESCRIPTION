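Package: genevec
Title: Gene and Sample Embeddings from Expression Matrices by Biased
    Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns low-dimensional gene and sample entity vectors from a
    log2 expression matrix by collaborative filtering: each expression
    value is modelled as the dot product of a gene vector and a sample
    vector plus gene and sample biases, fitted by mini-batch Adam on mean
    squared error. Includes Euclidean-threshold neighbor queries on the
    learned vectors, embedding-dimension interpretation via
    over-representation analysis (hypergeometric test with
    Benjamini-Hochberg correction), signature-dimension molecular
    subtyping with UPGMA clustering, a responder versus non-responder
    exclusive-neighbor biomarker discovery workflow, and a synthetic
    expression-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    methods,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
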