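Package: gskipgram
Title: Structure-Aware Skip-Gram Embedding of Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised node embedding for undirected (optionally weighted)
    networks such as protein-protein interaction graphs. Implements the
    Graph Skip-gram model, a random-walk skip-gram with negative sampling
    whose co-occurrence score is modulated by a graph-structure information
    function built from node degrees and shortest-path distances, together
    with Fioepn, a selective fusion of each node's input and output
    embeddings. Includes a stochastic-block-model generator, the Zachary
    karate-club fixture, and evaluation utilities for clustering quality
    (Calinski-Harabasz, within-group sum of squares), multi-label node
    classification, and link prediction with edge-feature operators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: igraph, glmnet, methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, Classification,
    DimensionReduction
RoxygenNote: 7.3.3
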