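Package: genomf
Title: Drug-Disease Association Prediction by Genomic-Space Matrix
    Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts novel drug indications by matrix factorization of
    known drug-disease associations, warm-started from genomic-space
    feature vectors.  Gene features are extracted from a gene interaction
    network through an exponential shortest-path closeness kernel followed
    by truncated eigendecomposition; drug and disease features are
    obtained by averaging the features of their interacting genes.  A
    sigmoid-output, L2-regularized factorization model is then trained by
    stochastic gradient descent on labeled drug-disease pairs.  Includes
    negative sampling, pair-, drug- and disease-wise cross-validation
    with ROC/AUC scoring, a synthetic-data generator with a planted
    genomic signal, TSV readers/writers for all artifacts, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    optparse,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
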