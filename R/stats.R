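#' Nine-statistic summary panel of a network
#'
#' Computes the statistic panel used to characterise musculoskeletal
#' network representations: node count |V|, (hyper)edge count |E|,
#' average node degree Avg.d(v), average (hyper)edge size Avg.|e|,
#' number of connected components CCs, size of the largest component
#' Larg.CC, global clustering coefficient GCC, density and diameter.
#'
#' Conventions: for a hypergraph, density is the ratio of hyperedges to
#' nodes |E|/|V|; connectivity, clustering and the diameter are
#' measured on the binary clique expansion, where two nodes are
#' adjacent iff they share a hyperedge. For a pairwise graph, density
#' is 2|E|/(|V|(|V|-1)) and Avg.|e| is identically 2. GCC is the
#' transitivity (3 x triangles / connected triples), a single global
#' quantity; the mean local clustering coefficient is also reported as
#' `gcc_local` for cross-checking, since the two conventions coexist in
#' the literature. The diameter is the longest shortest path inside the
#' largest connected component, in hops.
#'
#' The panel satisfies incidence conservation:
#' `|V| * Avg.d(v) = |E| * Avg.|e|` (both sides count incidences).
#'
#' @param x a [hypergraph()] or [pairwise_graph()].
#' @return an object of class `hg_stats`: a named list with fields
#'   `n_nodes`, `n_edges`, `avg_degree`, `avg_edge_size`,
#'   `n_components`, `largest_cc`, `gcc`, `gcc_local`, `density`,
#'   `diameter`.
#' @examples
#' hg <- fixture_mbm()
#' network_stats(hg)
#' @export
network_stats <- function(x) UseMethod("network_stats")

#' @export
network_stats.hypergraph <- function(x) {
  H <- incidence_matrix(x)
  g <- as_igraph(clique_expansion(x, "binary"))
  st <- .graph_panel(g)
  .hg_stats(
    n_nodes = length(x$nodes),
    n_edges = length(x$hyperedges),
    avg_degree = mean(rowSums(H)),
    avg_edge_size = mean(colSums(H)),
    n_components = st$n_components,
    largest_cc = st$largest_cc,
    gcc = st$gcc, gcc_local = st$gcc_local,
    density = length(x$hyperedges) / length(x$nodes),
    diameter = st$diameter)
}

#' @export
network_stats.pairwise_graph <- function(x) {
  g <- as_igraph(x)
  st <- .graph_panel(g)
  n <- length(x$nodes); m <- nrow(x$edges)
  .hg_stats(
    n_nodes = n, n_edges = m,
    avg_degree = if (n) 2 * m / n else 0,
    avg_edge_size = 2,
    n_components = st$n_components,
    largest_cc = st$largest_cc,
    gcc = st$gcc, gcc_local = st$gcc_local,
    density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    diameter = st$diameter)
}

.graph_panel <- function(g) {
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  gcc <- igraph::transitivity(g, type = "global")
  if (is.nan(gcc)) gcc <- 0
  gcc_local <- igraph::transitivity(g, type = "localaverage",
                                    isolates = "zero")
  if (is.nan(gcc_local)) gcc_local <- 0
  list(n_components = comp$no,
       largest_cc = max(comp$csize),
       gcc = gcc, gcc_local = gcc_local,
       diameter = if (igraph::vcount(giant) > 1)
         igraph::diameter(giant, weights = NA) else 0)
}

.hg_stats <- function(...) structure(list(...), class = "hg_stats")

#' @export
print.hg_stats <- function(x, ...) {
  v <- unlist(x)
  cat("|V|=", x$n_nodes, "  |E|=", x$n_edges,
      "  Avg.d(v)=", round(x$avg_degree, 2),
      "  Avg.|e|=", round(x$avg_edge_size, 2),
      "  CCs=", x$n_components, "  Larg.CC=", x$largest_cc,
      "  GCC=", round(x$gcc, 2),
      "  Density=", round(x$density, 2),
      "  Diameter=", x$diameter, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.hg_stats <- function(x, ...) {
  data.frame(n_nodes = x$n_nodes, n_edges = x$n_edges,
             avg_degree = x$avg_degree, avg_edge_size = x$avg_edge_size,
             n_components = x$n_components, largest_cc = x$largest_cc,
             gcc = x$gcc, gcc_local = x$gcc_local,
             density = x$density, diameter = x$diameter)
}

#' Write one or more statistic panels as TSV
#'
#' Columns follow the panel order |V|, |E|, Avg.d(v), Avg.|e|, CCs,
#' Larg.CC, GCC, Density, Diameter, preceded by a dataset name.
#'
#' @param stats a named list of `hg_stats` objects (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  if (inherits(stats, "hg_stats")) stats <- list(data = stats)
  rows <- vapply(names(stats), function(nm) {
    s <- stats[[nm]]
    paste(nm, s$n_nodes, s$n_edges,
          format(round(s$avg_degree, 2), nsmall = 2),
          format(round(s$avg_edge_size, 2), nsmall = 2),
          s$n_components, s$largest_cc,
          format(round(s$gcc, 2), nsmall = 2),
          format(round(s$density, 2), nsmall = 2),
          s$diameter, sep = "\t")
  }, character(1))
  writeLines(c("data\t|V|\t|E|\tAvg.d(v)\tAvg.|e|\tCCs\tLarg.CC\tGCC\tDensity\tDiameter",
               rows), path)
  invisible(path)
}
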