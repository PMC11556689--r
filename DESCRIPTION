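Package: hypermsk
Title: Hypergraph Embeddings for Musculoskeletal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the human musculoskeletal system as a muscle-bone
    bipartite network and its hypergraph and pairwise projections, and
    compares node-embedding methods on those representations. Provides
    hypergraph construction from bipartite edge lists, one-mode
    (clique-expansion) projections, a nine-statistic summary panel,
    seeded synthetic body-plan generators with planted spanning
    muscles, random-walk skip-gram embeddings (DeepWalk, node2vec),
    structural embeddings based on dynamic-time-warping degree-sequence
    distances for pairwise graphs (struc2vec) and hypergraphs
    (HyperS2V), spectral hypergraph-Laplacian embeddings (HHE), and
    standardized Euclidean distance profiles that expose muscles
    spanning several body parts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
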