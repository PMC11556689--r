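#' Positional bias terms of a hyper-degree list
#'
#' Each element s of a descending-sorted hyper-degree list HD gets the
#' bias `b_s = 1 / (max(HD) - s + 1)`, a "positional importance" in
#' (0, 1] that equals 1 for the largest element and decays for smaller
#' hyperedge sizes. By default the maximum is taken over the node's own
#' list; `global_max` substitutes a hypergraph-wide maximum so biases
#' are comparable across nodes (an alternative convention, off by
#' default).
#'
#' @param HD non-empty descending integer vector of hyperedge sizes.
#' @param global_max optional global maximum overriding `max(HD)`.
#' @return numeric vector of biases, same length as `HD`.
#' @examples
#' bias_terms(c(6, 5, 4))  # 1, 1/2, 1/3
#' @export
bias_terms <- function(HD, global_max = NULL) {
  if (!length(HD)) stop("empty hyper-degree list")
  m <- if (is.null(global_max)) max(HD) else global_max
  if (any(HD > m)) stop("hyper-degree element exceeds the stated maximum")
  1 / (m - HD + 1)
}

#' Magnitude-position distance between two hyper-degree elements
#'
#' Compares two hyperedge sizes together with their positional biases:
#' `mpd = exp((1 - min(s_i, s_j) / max(s_i, s_j))^2 + |b_i - b_j|^2) - 1`.
#' Zero iff both size and bias agree; symmetric. `mpd_sqrt = TRUE`
#' applies a square root to the exponent (a Euclidean-norm reading of
#' the same two terms), offered as a configurable alternative.
#'
#' @param s_i,s_j positive hyperedge sizes (vectorized).
#' @param b_i,b_j their bias terms.
#' @param mpd_sqrt use the square-root (Euclidean norm) exponent.
#' @return nonnegative numeric.
#' @export
mpd <- function(s_i, b_i, s_j, b_j, mpd_sqrt = FALSE) {
  if (any(s_i <= 0) || any(s_j <= 0)) stop("hyperedge sizes must be positive")
  ex <- (1 - pmin(s_i, s_j) / pmax(s_i, s_j))^2 + abs(b_i - b_j)^2
  if (mpd_sqrt) ex <- sqrt(ex)
  exp(ex) - 1
}

#' Hyper-degrees of all nodes
#'
#' @param hg a [hypergraph()].
#' @return named list of descending integer vectors, one per node.
#' @export
hyper_degrees <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- incidence_matrix(hg)
  sizes <- colSums(H)
  lapply(stats::setNames(hg$nodes, hg$nodes), function(v)
    sort(as.integer(sizes[H[v, ] == 1L]), decreasing = TRUE))
}

#' 0-hop structural distance between two hyper-degrees
#'
#' DTW over the two descending hyper-degree lists with [mpd()] as the
#' element cost, each element paired with its bias term. Zero iff the
#' lists are identical.
#'
#' @param HD_u,HD_v non-empty descending hyper-degree vectors.
#' @param mpd_sqrt,global_max passed to [mpd()] / [bias_terms()].
#' @return nonnegative DTW cost.
#' @examples
#' d0_hyper(c(2), c(2, 2))  # 0: one element matches both, biases all 1
#' @export
d0_hyper <- function(HD_u, HD_v, mpd_sqrt = FALSE, global_max = NULL) {
  if (!length(HD_u) || !length(HD_v))
    stop("degree-zero node: hyper-degree is empty")
  b_u <- bias_terms(HD_u, global_max)
  b_v <- bias_terms(HD_v, global_max)
  cm <- outer(seq_along(HD_u), seq_along(HD_v), function(i, j)
    mpd(HD_u[i], b_u[i], HD_v[j], b_v[j], mpd_sqrt))
  .dtw_dp(cm)
}

# Deterministic ordering of a k-hop neighbour ring: descending by
# (degree, total hyper-degree mass, label) so DTW sees a canonical
# sequence. The convention is a tie-break choice, recorded here.
.ring_order <- function(labels, HDs) {
  if (!length(labels)) return(character(0))
  deg <- lengths(HDs[labels])
  mass <- vapply(HDs[labels], sum, numeric(1))
  labels[order(-deg, -mass, labels)]
}

#' Layered structural distance table of a hypergraph
#'
#' The hypergraph analogue of [structural_distances()]: D_0(u, v) is
#' the DTW between the hyper-degrees of u and v under the
#' magnitude-position cost ([d0_hyper()]); for k > 0,
#' `D_k = D_{k-1} + DTW` between the ordered hyper-degree sequences of
#' the nodes exactly k hops from u and from v (hop distance in the
#' binary clique expansion), with the precomputed D_0 as element cost.
#' Pairs with an empty ring stop at the previous layer. Degree-zero
#' nodes are excluded with a warning.
#'
#' @param hg a [hypergraph()].
#' @param k_max deepest layer; defaults to the clique-expansion
#'   diameter, capped at 5.
#' @param mpd_sqrt,global_max element-cost options; `global_max = TRUE`
#'   uses the hypergraph-wide maximum hyperedge size for bias terms.
#' @return a `distance_table` (see [structural_distances()]).
#' @export
hyper_distances <- function(hg, k_max = NULL, mpd_sqrt = FALSE,
                            global_max = FALSE) {
  stopifnot(inherits(hg, "hypergraph"))
  HDs <- hyper_degrees(hg)
  deg0 <- names(HDs)[lengths(HDs) == 0L]
  if (length(deg0)) {
    warning("excluding degree-zero nodes: ", paste(deg0, collapse = ", "))
    HDs <- HDs[lengths(HDs) > 0L]
  }
  nodes <- names(HDs)
  if (length(nodes) < 2) stop("need at least two positive-degree nodes")
  gmax <- if (isTRUE(global_max)) max(unlist(HDs)) else NULL

  n <- length(nodes)
  D0 <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      D0[i, j] <- D0[j, i] <- d0_hyper(HDs[[i]], HDs[[j]], mpd_sqrt, gmax)

  ig <- as_igraph(clique_expansion(hg, "binary"))
  sp <- igraph::distances(ig, v = nodes, to = nodes, weights = NA)
  if (is.null(k_max))
    k_max <- min(5L, max(sp[is.finite(sp)]))
  rings <- lapply(stats::setNames(nodes, nodes), function(u) {
    lapply(0:k_max, function(k)
      .ring_order(colnames(sp)[which(sp[u, ] == k)], HDs))
  })
  .accumulate_layers(nodes, k_max, d0 = D0,
                     ring_cost = function(u, v, k) {
                       ru <- rings[[u]][[k + 1L]]
                       rv <- rings[[v]][[k + 1L]]
                       if (!length(ru) || !length(rv)) return(NA_real_)
                       .dtw_dp(D0[ru, rv, drop = FALSE])
                     })
}

#' Layer-k structural distance between two hypergraph nodes
#'
#' Convenience accessor computing [hyper_distances()] up to layer `k`
#' and returning the (u, v) entry.
#'
#' @param hg a [hypergraph()].
#' @param u,v node labels.
#' @param k layer, >= 0.
#' @param ... passed to [hyper_distances()].
#' @return numeric distance (NA if the pair is absent from layer `k`).
#' @export
dk_hyper <- function(hg, u, v, k, ...) {
  stopifnot(k >= 0)
  tab <- hyper_distances(hg, k_max = k, ...)
  if (!u %in% tab$nodes || !v %in% tab$nodes) stop("unknown node")
  tab$D[[k + 1L]][u, v]
}

#' HyperS2V structural embedding of a hypergraph
#'
#' Pipeline: hyper-degree DTW distances ([hyper_distances()]),
#' multilayer context graph with weights `exp(-D_k)`
#' ([build_multilayer()]), biased multilayer walks, skip-gram. Unlike
#' clique-expansion methods this sees hyperedge sizes directly, so
#' muscles with similar bone-attachment profiles embed close together
#' regardless of where they sit in the body.
#'
#' @inheritParams hyper_distances
#' @inheritParams multilayer_walks
#' @inheritParams train_skipgram
#' @return an `embedding_matrix` (positive-degree nodes x dim).
#' @export
embed_hypers2v <- function(hg, dim = 16L, k_max = NULL, q_stay = 0.7,
                           walks_per_node = 10L, walk_length = 80L,
                           window = 5L, epochs = 5L,
                           objective = "negative_sampling", seed = 1L,
                           mpd_sqrt = FALSE, global_max = FALSE) {
  table <- hyper_distances(hg, k_max, mpd_sqrt, global_max)
  ml <- build_multilayer(table)
  corpus <- multilayer_walks(ml, walks_per_node, walk_length, q_stay, seed)
  emb <- train_skipgram(corpus, dim, window, epochs, objective, seed = seed,
                        nodes = ml$nodes)
  attr(emb, "method") <- "hypers2v"
  emb
}
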