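Package: ksmc
Title: Kinase-Substrate Interaction Prediction by Matrix Completion on a
    Heterogeneous Sequence-Similarity Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts kinase-substrate phosphorylation interactions from
    protein sequences and a sparse list of known interactions. Pairwise
    kinase-kinase and substrate-substrate similarities are computed by
    Smith-Waterman local alignment (BLOSUM62, affine gaps), the bipartite
    interaction network is augmented with edges between kinases and
    substrates highly similar to known partners, and the resulting
    heterogeneous block matrix is completed by singular value thresholding
    (nuclear-norm relaxation of rank minimization). Includes ten-fold
    cross-validation and de-novo (leave-one-kinase-out) evaluation
    protocols with ROC/AUC summaries, and a synthetic block-model data
    generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
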