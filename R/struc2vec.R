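#' Degree-ratio distance between two node degrees
#'
#' The 0-hop structural distance between two nodes of degrees `d_u`
#' and `d_v`: `max(d_u, d_v) / min(d_u, d_v) - 1`. Zero iff the degrees
#' are equal; symmetric; grows with the degree ratio, so that e.g.
#' degrees 1 vs 2 differ more than 100 vs 101.
#'
#' @param d_u,d_v positive degrees (vectorized).
#' @return nonnegative numeric.
#' @export
d0_pair <- function(d_u, d_v) {
  if (any(d_u <= 0) || any(d_v <= 0))
    stop("degrees must be positive; degree-zero nodes are excluded upstream")
  pmax(d_u, d_v) / pmin(d_u, d_v) - 1
}

#' Dynamic time warping distance between two sequences
#'
#' Classic dynamic-programming DTW with boundary matching, monotone
#' steps \{(1,0), (0,1), (1,1)\} and no band constraint: the minimal
#' cumulative element cost over all monotone alignments of the two
#' sequences.
#'
#' @param a,b non-empty numeric vectors.
#' @param cost vectorized element-cost function `f(x, y)`; defaults to
#'   absolute difference.
#' @return the minimal cumulative alignment cost.
#' @examples
#' dtw(c(3, 1), 2)            # |3-2| + |1-2| = 2
#' dtw(1:4, 1:4)              # 0
#' @export
dtw <- function(a, b, cost = function(x, y) abs(x - y)) {
  if (!length(a) || !length(b)) stop("DTW requires non-empty sequences")
  .dtw_dp(outer(a, b, cost))
}

.sorted_rings <- function(dists, degs, k_max) {
  # rings[[u]][[k+1]] = ascending degrees of nodes exactly k hops from u
  nodes <- rownames(dists)
  lapply(stats::setNames(nodes, nodes), function(u) {
    lapply(0:k_max, function(k) {
      at_k <- colnames(dists)[which(dists[u, ] == k)]
      sort(degs[at_k])
    })
  })
}

#' Structural distance table of a pairwise graph
#'
#' For every node pair (u, v), a per-layer structural distance D_k:
#' D_0 compares the root degrees via [d0_pair()], and for k > 0,
#' `D_k = D_{k-1} + DTW` between the ascending-sorted degree sequences
#' of the nodes exactly k hops from u and from v, with [d0_pair()] as
#' the element cost. If either k-hop ring is empty the pair stops
#' accumulating and is absent (NA) from layer k on. Degree-zero nodes
#' are excluded with a warning. D_k is symmetric, zero on the diagonal
#' and non-decreasing in k.
#'
#' @param g a [pairwise_graph()].
#' @param k_max deepest layer; defaults to the diameter of the largest
#'   component, capped at 5.
#' @return an object of class `distance_table`: list with `nodes`,
#'   `k_max`, and `D`, a list of `k_max + 1` symmetric matrices (NA
#'   marks pairs absent from a layer).
#' @export
structural_distances <- function(g, k_max = NULL) {
  stopifnot(inherits(g, "pairwise_graph"))
  ig <- as_igraph(g)
  degs <- igraph::degree(ig)
  if (any(degs == 0)) {
    warning("excluding degree-zero nodes: ",
            paste(names(degs)[degs == 0], collapse = ", "))
    ig <- igraph::induced_subgraph(ig, which(degs > 0))
    degs <- igraph::degree(ig)
  }
  if (igraph::vcount(ig) < 2) stop("need at least two positive-degree nodes")
  sp <- igraph::distances(ig, weights = NA)
  if (is.null(k_max))
    k_max <- min(5L, max(sp[is.finite(sp)]))
  nodes <- igraph::V(ig)$name
  rings <- .sorted_rings(sp, degs, k_max)
  .accumulate_layers(nodes, k_max,
                     d0 = outer(degs, degs, d0_pair),
                     ring_cost = function(u, v, k) {
                       ru <- rings[[u]][[k + 1L]]
                       rv <- rings[[v]][[k + 1L]]
                       if (!length(ru) || !length(rv)) return(NA_real_)
                       .dtw_dp(outer(ru, rv, d0_pair))
                     })
}

# Shared layer-accumulation driver for both structural distance tables.
.accumulate_layers <- function(nodes, k_max, d0, ring_cost) {
  n <- length(nodes)
  D <- vector("list", k_max + 1L)
  D0 <- matrix(0, n, n, dimnames = list(nodes, nodes))
  D0[, ] <- d0
  diag(D0) <- 0
  D[[1L]] <- D0
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) {
      Dk <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
      diag(Dk) <- 0
      prev <- D[[k]]
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          if (is.na(prev[i, j])) next
          add <- ring_cost(nodes[i], nodes[j], k)
          if (is.na(add)) next
          Dk[i, j] <- Dk[j, i] <- prev[i, j] + add
        }
      }
      D[[k + 1L]] <- Dk
    }
  }
  structure(list(nodes = nodes, k_max = k_max, D = D),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table> ", length(x$nodes), " nodes, layers 0..",
      x$k_max, "\n", sep = "")
  invisible(x)
}

#' Export a layered distance table as long-format TSV
#'
#' Columns `u`, `v`, `k`, `D_k`, one row per pair per layer where the
#' pair is present.
#'
#' @param table a `distance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(table, path) {
  stopifnot(inherits(table, "distance_table"))
  rows <- character(0)
  for (k in 0:table$k_max) {
    M <- table$D[[k + 1L]]
    idx <- which(upper.tri(M) & !is.na(M), arr.ind = TRUE)
    if (nrow(idx))
      rows <- c(rows, paste(table$nodes[idx[, 1L]], table$nodes[idx[, 2L]],
                            k, M[idx], sep = "\t"))
  }
  writeLines(c("u\tv\tk\tD_k", rows), path)
  invisible(path)
}

#' Multilayer context graph from a structural distance table
#'
#' One layer per distance depth k, each holding a copy of every node.
#' Intra-layer edges connect pairs present at layer k with weight
#' `w_k(u, v) = exp(-D_k(u, v))`, so weight 1 iff distance 0. A node's
#' copies in consecutive layers are linked; the upward weight from
#' layer k to k + 1 is `log(Gamma_k(u) + e)`, where `Gamma_k(u)` counts
#' the intra-layer edges at u whose weight exceeds the layer mean
#' (nodes similar to many others are pushed up to more discriminative
#' layers); the downward weight is 1.
#'
#' @param table a `distance_table` from [structural_distances()] or
#'   [hyper_distances()].
#' @return an object of class `multilayer_context_graph`: list with
#'   `nodes`, `k_max`, `w` (per-layer weight matrices) and `up`
#'   (node-by-layer upward weights).
#' @export
build_multilayer <- function(table) {
  stopifnot(inherits(table, "distance_table"))
  n <- length(table$nodes)
  w <- vector("list", table$k_max + 1L)
  up <- matrix(1, n, table$k_max + 1L, dimnames = list(table$nodes, NULL))
  for (k in 0:table$k_max) {
    W <- exp(-table$D[[k + 1L]])
    diag(W) <- NA_real_                    # no self-edges inside a layer
    w[[k + 1L]] <- W
    off <- W[upper.tri(W)]
    mbar <- mean(off, na.rm = TRUE)
    gamma <- vapply(seq_len(n), function(i)
      sum(W[i, ] > mbar, na.rm = TRUE), numeric(1))
    up[, k + 1L] <- log(gamma + exp(1))
  }
  structure(list(nodes = table$nodes, k_max = table$k_max, w = w, up = up),
            class = "multilayer_context_graph")
}

#' @export
print.multilayer_context_graph <- function(x, ...) {
  cat("<multilayer_context_graph> ", length(x$nodes), " nodes, layers 0..",
      x$k_max, "\n", sep = "")
  invisible(x)
}

#' Random walks on a multilayer context graph
#'
#' At each step the walker stays in its layer with probability
#' `q_stay`, moving to another node copy with probability proportional
#' to the intra-layer weight w_k; otherwise it switches layer, choosing
#' up vs down in proportion to the up/down weights (down weight 1).
#' Only moves to a different node append to the emitted sequence, so
#' walks project onto base node labels.
#'
#' @param ml a `multilayer_context_graph`.
#' @param walks_per_node,walk_length,seed as in [uniform_walks()].
#' @param q_stay probability of an intra-layer move.
#' @return a `walk_corpus`.
#' @export
multilayer_walks <- function(ml, walks_per_node = 10L, walk_length = 80L,
                             q_stay = 0.7, seed = 1L) {
  stopifnot(inherits(ml, "multilayer_context_graph"),
            q_stay > 0, q_stay <= 1)
  set.seed(seed)
  n <- length(ml$nodes)
  walks <- vector("list", n * walks_per_node)
  widx <- 0L
  for (i in seq_len(n)) {
    for (r in seq_len(walks_per_node)) {
      cur <- i; layer <- 0L
      walk <- character(walk_length)
      walk[1L] <- ml$nodes[i]
      len <- 1L
      guard <- 0L
      while (len < walk_length && guard < 20L * walk_length) {
        guard <- guard + 1L
        wrow <- ml$w[[layer + 1L]][cur, ]
        nb <- which(!is.na(wrow) & wrow > 0)
        if (length(nb) && stats::runif(1) < q_stay) {
          cur <- nb[sample.int(length(nb), 1L, prob = wrow[nb])]
          len <- len + 1L
          walk[len] <- ml$nodes[cur]
        } else {
          up_w <- if (layer < ml$k_max) ml$up[cur, layer + 1L] else 0
          down_w <- if (layer > 0L) 1 else 0
          if (up_w + down_w == 0) next
          layer <- if (stats::runif(1) < up_w / (up_w + down_w))
            layer + 1L else layer - 1L
        }
      }
      widx <- widx + 1L
      walks[[widx]] <- walk[seq_len(len)]
    }
  }
  .walk_corpus(walks, walk_length, walks_per_node, seed)
}

#' struc2vec structural embedding of a pairwise graph
#'
#' Pipeline: per-layer degree-sequence DTW distances
#' ([structural_distances()]), multilayer context graph
#' ([build_multilayer()]), biased multilayer walks, skip-gram. Places
#' nodes with similar topological roles (degree, neighbour degrees,
#' ...) close together even when they sit in different components.
#'
#' @inheritParams structural_distances
#' @inheritParams multilayer_walks
#' @inheritParams train_skipgram
#' @return an `embedding_matrix` (positive-degree nodes x dim).
#' @export
embed_struc2vec <- function(g, dim = 16L, k_max = NULL, q_stay = 0.7,
                            walks_per_node = 10L, walk_length = 80L,
                            window = 5L, epochs = 5L,
                            objective = "negative_sampling", seed = 1L) {
  if (inherits(g, "hypergraph")) g <- clique_expansion(g, "binary")
  table <- structural_distances(g, k_max)
  ml <- build_multilayer(table)
  corpus <- multilayer_walks(ml, walks_per_node, walk_length, q_stay, seed)
  emb <- train_skipgram(corpus, dim, window, epochs, objective, seed = seed,
                        nodes = ml$nodes)
  attr(emb, "method") <- "struc2vec"
  emb
}
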