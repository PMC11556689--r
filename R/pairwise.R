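#' Simple weighted pairwise graph
#'
#' Undirected simple graph with nonnegative real edge weights and no
#' self-loops; diagonal information (for projection matrices) is stored
#' separately in `diagonal`.
#'
#' @param nodes character vector of node labels.
#' @param edges data frame with columns `u`, `v` and optionally
#'   `weight` (default 1); unordered duplicates collapse, keeping the
#'   first weight.
#' @param diagonal optional named numeric vector of per-node diagonal
#'   metadata (e.g. hypergraph node degrees).
#' @return an object of class `pairwise_graph`.
#' @export
pairwise_graph <- function(nodes, edges, diagonal = NULL) {
  nodes <- trimws(as.character(nodes))
  if (!length(nodes)) stop("empty node set")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(u = character(0), v = character(0), weight = numeric(0))
  } else {
    u <- trimws(as.character(edges[[1L]]))
    v <- trimws(as.character(edges[[2L]]))
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
         else if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(u))
    if (any(u == v)) stop("self-loops are not allowed in the edge set")
    if (any(w < 0)) stop("edge weights must be nonnegative")
    if (length(bad <- setdiff(c(u, v), nodes)))
      stop("edge endpoint not in node set: ", paste(bad, collapse = ", "))
    key <- ifelse(u < v, paste(u, v, sep = "\r"), paste(v, u, sep = "\r"))
    keep <- !duplicated(key)
    edges <- data.frame(u = u[keep], v = v[keep], weight = w[keep],
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, diagonal = diagonal),
            class = "pairwise_graph")
}

#' @export
print.pairwise_graph <- function(x, ...) {
  cat("<pairwise_graph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a pairwise graph to an igraph object
#'
#' @param pg a [pairwise_graph()].
#' @return an undirected weighted [igraph::igraph] graph.
#' @export
as_igraph <- function(pg) {
  stopifnot(inherits(pg, "pairwise_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(pg$nodes), name = pg$nodes)
  if (nrow(pg$edges))
    g <- igraph::add_edges(g, rbind(pg$edges$u, pg$edges$v),
                           weight = pg$edges$weight)
  g
}

#' Clique expansion of a hypergraph
#'
#' Connects every pair of nodes that co-occur in at least one
#' hyperedge. For the muscle-centric hypergraph this equals the
#' one-mode projection of the bipartite muscle-bone network: the
#' complete graph over the muscles of every bone. Weighting `"binary"`
#' gives weight 1 per adjacent pair; `"shared_count"` weights by the
#' number of shared hyperedges (common bones). The diagonal metadata of
#' the result records the hypergraph node degrees d(v).
#'
#' @param hg a [hypergraph()].
#' @param weighting `"binary"` or `"shared_count"`.
#' @return a [pairwise_graph()].
#' @export
clique_expansion <- function(hg, weighting = c("binary", "shared_count")) {
  stopifnot(inherits(hg, "hypergraph"))
  weighting <- match.arg(weighting)
  H <- incidence_matrix(hg)
  S <- H %*% t(H)
  diag(S) <- 0L
  idx <- which(S > 0 & upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(u = rownames(S)[idx[, 1L]],
                      v = colnames(S)[idx[, 2L]],
                      weight = if (weighting == "binary") rep(1, nrow(idx))
                               else as.numeric(S[idx]),
                      stringsAsFactors = FALSE)
  pairwise_graph(hg$nodes, edges,
                 diagonal = stats::setNames(as.numeric(rowSums(H)), hg$nodes))
}
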