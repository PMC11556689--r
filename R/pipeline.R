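#' Embed muscles with a named method
#'
#' Dispatcher over the five embedding methods. Pairwise methods
#' (deepwalk, node2vec, struc2vec) run on the binary clique expansion
#' of the hypergraph - the muscle-centric one-mode projection - while
#' hhe and hypers2v consume the hypergraph directly.
#'
#' @param hg a [hypergraph()] (muscle-centric).
#' @param method one of `"deepwalk"`, `"node2vec"`, `"struc2vec"`,
#'   `"hhe"`, `"hypers2v"`.
#' @param dim embedding dimension (for `"hhe"`, capped at the number
#'   of nonzero Laplacian eigenvalues).
#' @param seed integer RNG seed (ignored by the deterministic `"hhe"`).
#' @param ... method-specific options (e.g. `p`, `q`, `q_stay`,
#'   `mpd_sqrt`).
#' @return an `embedding_matrix`.
#' @export
embed_muscles <- function(hg, method = c("hypers2v", "deepwalk", "node2vec",
                                         "struc2vec", "hhe"),
                          dim = 16L, seed = 1L, ...) {
  stopifnot(inherits(hg, "hypergraph"))
  method <- match.arg(method)
  switch(method,
    deepwalk = embed_deepwalk(hg, dim = dim, seed = seed, ...),
    node2vec = embed_node2vec(hg, dim = dim, seed = seed, ...),
    struc2vec = embed_struc2vec(hg, dim = dim, seed = seed, ...),
    hypers2v = embed_hypers2v(hg, dim = dim, seed = seed, ...),
    hhe = {
      comp <- igraph::components(as_igraph(clique_expansion(hg, "binary")))
      k <- min(dim, length(hg$nodes) - comp$no)
      embed_hhe(hg, k = k, ...)
    })
}

#' Standardized muscle-muscle distance matrix for a method
#'
#' Runs [embed_muscles()], z-scores the embedding dimensions and
#' returns the pairwise Euclidean distance matrix.
#'
#' @inheritParams embed_muscles
#' @return a `distance_matrix`.
#' @export
muscle_distances <- function(hg, method = "hypers2v", dim = 16L, seed = 1L,
                             ...) {
  euclidean_distances(standardize(embed_muscles(hg, method, dim, seed, ...)))
}

#' Compare embedding methods by spanning-muscle separation
#'
#' For a synthetic body-plan network with known planted spanning
#' muscles, computes the [spanning_separation()] score of each method
#' for each seed.
#'
#' @param syn a `synthetic_bipartite` from [generate_bipartite()].
#' @param methods character vector of method names (see
#'   [embed_muscles()]).
#' @param seeds integer vector of embedding seeds.
#' @param dim embedding dimension.
#' @param ... passed to [embed_muscles()].
#' @return a seeds-by-methods numeric matrix of separation scores.
#' @export
compare_methods <- function(syn, methods = c("hypers2v", "deepwalk",
                                             "node2vec", "struc2vec", "hhe"),
                            seeds = 1:5, dim = 16L, ...) {
  stopifnot(inherits(syn, "synthetic_bipartite"))
  hg <- project_hypergraph(syn$network, "muscle")
  hg$parts <- syn$parts
  hg$spanning <- syn$spanning
  span <- names(which(syn$spanning))
  out <- matrix(NA_real_, length(seeds), length(methods),
                dimnames = list(as.character(seeds), methods))
  for (m in methods) {
    for (i in seq_along(seeds)) {
      D <- muscle_distances(hg, method = m, dim = dim, seed = seeds[i], ...)
      out[i, m] <- spanning_separation(D, span, syn$parts)$score
    }
  }
  out
}
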