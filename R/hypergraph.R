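#' Hypergraph of labelled nodes and hyperedges
#'
#' A hypergraph is a node set plus labelled hyperedges, each a non-empty
#' subset of the nodes. In the muscle-centric musculoskeletal view the
#' nodes are muscles and every bone is a hyperedge containing the
#' muscles attached to it; the size of a hyperedge |e| is then the
#' number of muscles on that bone and the degree d(v) of a muscle is the
#' number of bones it attaches to. Hyperedges with identical member sets
#' are kept distinct: they stand for distinct bones.
#'
#' @param nodes character vector of node labels (first-appearance order
#'   is preserved for all matrix layouts).
#' @param hyperedges named list of character vectors, one per hyperedge.
#' @param parts optional named character vector assigning a body part to
#'   every node.
#' @param spanning optional named logical flagging nodes that span
#'   several body parts.
#' @return an object of class `hypergraph`.
#' @export
hypergraph <- function(nodes, hyperedges, parts = NULL, spanning = NULL) {
  nodes <- trimws(as.character(nodes))
  if (!length(nodes)) stop("empty node set")
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (!length(hyperedges)) stop("hypergraph needs at least one hyperedge")
  if (is.null(names(hyperedges)) || any(!nzchar(names(hyperedges))))
    names(hyperedges) <- paste0("e", seq_along(hyperedges))
  hyperedges <- lapply(hyperedges, function(e) unique(trimws(as.character(e))))
  sizes <- lengths(hyperedges)
  if (any(sizes == 0L)) stop("hyperedges must be non-empty")
  members <- unique(unlist(hyperedges, use.names = FALSE))
  if (length(bad <- setdiff(members, nodes)))
    stop("hyperedge member not in node set: ", paste(bad, collapse = ", "))
  structure(list(nodes = nodes, hyperedges = hyperedges,
                 parts = parts, spanning = spanning),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("<hypergraph> ", length(x$nodes), " nodes, ",
      length(x$hyperedges), " hyperedges (sizes ",
      min(lengths(x$hyperedges)), "-", max(lengths(x$hyperedges)), ")\n",
      sep = "")
  invisible(x)
}

#' Binary incidence matrix of a hypergraph
#'
#' Rows are nodes, columns hyperedges; entry 1 iff the node belongs to
#' the hyperedge. Column sums are hyperedge sizes, row sums node degrees.
#'
#' @param hg a [hypergraph()].
#' @return an integer matrix with dimnames.
#' @export
incidence_matrix <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- matrix(0L, length(hg$nodes), length(hg$hyperedges),
              dimnames = list(hg$nodes, names(hg$hyperedges)))
  for (j in seq_along(hg$hyperedges))
    H[hg$hyperedges[[j]], j] <- 1L
  H
}

#' Project a bipartite network onto a hypergraph
#'
#' `center = "muscle"` gives the muscle-centric hypergraph (MbM): nodes
#' are muscles and each bone becomes a hyperedge containing its attached
#' muscles. `center = "bone"` gives the dual bone-centric hypergraph
#' (BmB). Bones (resp. muscles) attached to nothing produce no
#' hyperedge; isolated nodes on the centred side are kept as
#' degree-zero nodes.
#'
#' @param bip a [bipartite_network()].
#' @param center `"muscle"` or `"bone"`.
#' @return a [hypergraph()].
#' @export
project_hypergraph <- function(bip, center = c("muscle", "bone")) {
  stopifnot(inherits(bip, "bipartite_network"))
  center <- match.arg(center)
  if (!nrow(bip$edges)) stop("degenerate projection: bipartite edge set is empty")
  if (center == "muscle") {
    he <- split(bip$edges$muscle, factor(bip$edges$bone, levels = bip$bones))
    he <- he[lengths(he) > 0L]
    hypergraph(bip$muscles, he)
  } else {
    he <- split(bip$edges$bone, factor(bip$edges$muscle, levels = bip$muscles))
    he <- he[lengths(he) > 0L]
    hypergraph(bip$bones, he)
  }
}

#' Dual of a hypergraph
#'
#' Swaps the roles of nodes and hyperedges: the dual has one node per
#' hyperedge and one hyperedge per original node (its set of incident
#' hyperedges); the incidence matrix is transposed. Degree-zero nodes
#' would give empty dual hyperedges and are dropped. Applying the dual
#' twice returns a hypergraph isomorphic to the original (up to
#' degree-zero nodes).
#'
#' @param hg a [hypergraph()].
#' @return a [hypergraph()].
#' @export
dual_hypergraph <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- incidence_matrix(hg)
  deg <- rowSums(H)
  he <- lapply(hg$nodes[deg > 0L], function(v)
    names(hg$hyperedges)[H[v, ] == 1L])
  names(he) <- hg$nodes[deg > 0L]
  hypergraph(names(hg$hyperedges), he)
}

#' Hyper-degree of a node
#'
#' The hyper-degree HD of a node is the descending-sorted list of the
#' sizes of the hyperedges containing it; its length is the node degree
#' d(v). A degree-zero node has an empty hyper-degree.
#'
#' @param hg a [hypergraph()].
#' @param v node label.
#' @return integer vector, sorted descending.
#' @export
hyper_degree <- function(hg, v) {
  stopifnot(inherits(hg, "hypergraph"))
  if (!v %in% hg$nodes) stop("unknown node: ", v)
  sizes <- lengths(hg$hyperedges)[vapply(hg$hyperedges, function(e) v %in% e,
                                         logical(1))]
  sort(as.integer(sizes), decreasing = TRUE)
}

#' Size-filtered degree of a node
#'
#' Number of hyperedges containing `v` whose size is at least `s_min`;
#' non-increasing in `s_min` and equal to d(v) at `s_min = 1`. This is
#' the hyper-degree panel quantity: how many bones of a muscle connect
#' at least `s_min` muscles.
#'
#' @param hg a [hypergraph()].
#' @param v node label.
#' @param s_min minimum hyperedge size, >= 1.
#' @return integer count.
#' @export
filtered_degree <- function(hg, v, s_min = 1L) {
  stopifnot(s_min >= 1L)
  sum(hyper_degree(hg, v) >= s_min)
}

#' Weighted adjacency matrices of a hypergraph
#'
#' Two weighting schemes over the node-node adjacency induced by shared
#' hyperedges. `"shared_count"`: off-diagonal entries count the
#' hyperedges shared by the pair (for muscles: common bones), the
#' diagonal carries the node degrees d(v). `"neighbor_degree"`: entry
#' (u, v) carries, for adjacent pairs, the number of distinct neighbours
#' of v in the clique expansion (its pairwise degree), and the diagonal
#' is empty (zero).
#'
#' @param hg a [hypergraph()].
#' @param scheme `"shared_count"` or `"neighbor_degree"`.
#' @return a numeric node-by-node matrix.
#' @export
weighted_adjacency <- function(hg, scheme = c("shared_count", "neighbor_degree")) {
  scheme <- match.arg(scheme)
  H <- incidence_matrix(hg)
  shared <- H %*% t(H)              # off-diagonal: common hyperedges
  A <- (shared > 0) * 1L
  diag(A) <- 0L
  if (scheme == "shared_count") {
    W <- shared
    diag(W) <- rowSums(H)
  } else {
    nbr_deg <- rowSums(A)
    W <- A * rep(nbr_deg, each = nrow(A))  # column v carries deg(v)
    diag(W) <- 0
  }
  storage.mode(W) <- "double"
  W
}

#' Write a hypergraph as a hyperedge list
#'
#' One hyperedge per line: `edge_label TAB comma-separated members`.
#'
#' @param hg a [hypergraph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hyperedges <- function(hg, path) {
  stopifnot(inherits(hg, "hypergraph"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(hg$hyperedges),
                   vapply(hg$hyperedges, paste, character(1), collapse = ","),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a hyperedge-list file written by [write_hyperedges()]
#'
#' @param path input file path.
#' @return a [hypergraph()].
#' @export
read_hyperedges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no hyperedges in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed hyperedge at line ", bad[1L], " of ", path)
  he <- lapply(parts, function(p) strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(he) <- vapply(parts, `[`, character(1), 1L)
  hypergraph(unique(unlist(he, use.names = FALSE)), he)
}
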