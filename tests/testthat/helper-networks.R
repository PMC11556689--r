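# Programmatic fixtures and independent oracles shared across tests.

# Random bipartite muscle-bone network; every muscle gets >= 1 bone.
rand_bipartite <- function(n_muscles, n_bones, p = 0.3, seed = 1) {
  set.seed(seed)
  muscles <- sprintf("M%02d", seq_len(n_muscles))
  bones <- sprintf("B%02d", seq_len(n_bones))
  em <- character(0); eb <- character(0)
  for (m in muscles) {
    att <- bones[runif(n_bones) < p]
    if (!length(att)) att <- sample(bones, 1)
    em <- c(em, rep(m, length(att))); eb <- c(eb, att)
  }
  bipartite_network(data.frame(muscle = em, bone = eb),
                    muscles = muscles,
                    bones = bones[bones %in% unique(eb)])
}

# Random hypergraph with given node/edge counts and edge sizes in
# [1, max_size]; every node is placed in >= 1 hyperedge.
rand_hypergraph <- function(n_nodes, n_edges, max_size = 4, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  he <- lapply(seq_len(n_edges), function(j)
    sample(nodes, sample.int(min(max_size, n_nodes), 1)))
  names(he) <- sprintf("e%02d", seq_len(n_edges))
  lonely <- setdiff(nodes, unique(unlist(he)))
  for (v in lonely) {
    j <- sample.int(n_edges, 1)
    he[[j]] <- unique(c(he[[j]], v))
  }
  hypergraph(nodes, he)
}

# Random simple graph as a pairwise_graph (via igraph G(n, m)).
rand_graph <- function(n, m, seed = 1) {
  set.seed(seed)
  m <- min(m, n * (n - 1) / 2)
  g <- igraph::sample_gnm(n, m)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  pg_from_igraph(g)
}

pg_from_igraph <- function(g) {
  e <- igraph::as_edgelist(g)
  pairwise_graph(igraph::V(g)$name,
                 data.frame(u = e[, 1], v = e[, 2],
                            weight = igraph::E(g)$weight %||% rep(1, nrow(e))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-alignment DTW oracle: plain recursion over all monotone
# warping paths, no dynamic program shared with the implementation.
dtw_oracle <- function(a, b, cost = function(x, y) abs(x - y)) {
  rec <- function(i, j) {
    c0 <- cost(a[i], b[j])
    if (i == 1 && j == 1) return(c0)
    cands <- c()
    if (i > 1) cands <- c(cands, rec(i - 1, j))
    if (j > 1) cands <- c(cands, rec(i, j - 1))
    if (i > 1 && j > 1) cands <- c(cands, rec(i - 1, j - 1))
    c0 + min(cands)
  }
  rec(length(a), length(b))
}

# Brute-force one-mode projection of a bipartite network by a
# common-neighbour scan (independent of clique_expansion).
brute_projection <- function(bip) {
  ms <- bip$muscles
  adj <- lapply(ms, function(m) bip$edges$bone[bip$edges$muscle == m])
  names(adj) <- ms
  rows <- list()
  for (i in seq_along(ms)) for (j in seq_len(i - 1L)) {
    shared <- length(intersect(adj[[ms[i]]], adj[[ms[j]]]))
    if (shared > 0)
      rows[[length(rows) + 1L]] <- data.frame(u = ms[j], v = ms[i],
                                              weight = shared)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Duplicate a hypergraph into two disjoint isomorphic components.
duplicate_hypergraph <- function(hg, suffix = ".2") {
  he2 <- c(hg$hyperedges,
           lapply(hg$hyperedges, function(e) paste0(e, suffix)))
  names(he2) <- c(names(hg$hyperedges),
                  paste0(names(hg$hyperedges), suffix))
  hypergraph(c(hg$nodes, paste0(hg$nodes, suffix)), he2)
}

# Two disjoint isomorphic "lollipop" components (triangle + tail):
# nodes c, d, e have unique structural roles in each copy.
twin_lollipops <- function() {
  edges <- function(pre) data.frame(
    u = paste0(pre, c("a", "a", "b", "c", "d")),
    v = paste0(pre, c("b", "c", "c", "d", "e")))
  pairwise_graph(c(paste0("x", letters[1:5]), paste0("y", letters[1:5])),
                 rbind(edges("x"), edges("y")))
}

nearest_neighbour <- function(D, u) {
  names(which.min(D[u, setdiff(colnames(D), u)]))
}
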