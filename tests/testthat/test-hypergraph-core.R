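test_that("bipartite projection builds the muscle-centric hypergraph and its dual", {
  bip <- bipartite_network(data.frame(muscle = c("A", "B"), bone = c("x", "x")))
  hg <- project_hypergraph(bip, "muscle")
  expect_equal(length(hg$nodes), 2L)
  expect_equal(length(hg$hyperedges), 1L)
  expect_setequal(hg$hyperedges[[1]], c("A", "B"))

  # bone-centric projection equals the dual of the muscle-centric one
  for (seed in 1:5) {
    b <- rand_bipartite(8, 12, 0.3, seed)
    mbm <- project_hypergraph(b, "muscle")
    bmb <- project_hypergraph(b, "bone")
    dual <- dual_hypergraph(mbm)
    expect_setequal(dual$nodes, bmb$nodes)
    key <- function(hg) sort(vapply(hg$hyperedges,
                                    function(e) paste(sort(e), collapse = ","),
                                    character(1)))
    expect_equal(key(dual), key(bmb))
  }

  empty <- bipartite_network(data.frame(muscle = "A", bone = "x"))
  empty$edges <- empty$edges[0, ]
  expect_error(project_hypergraph(empty, "muscle"), "degenerate")
})

test_that("dual of the dual is isomorphic to the original", {
  hg1 <- hypergraph(c("A", "B"), list(e1 = c("A", "B")))
  d1 <- dual_hypergraph(hg1)
  expect_equal(length(d1$nodes), 1L)
  expect_equal(lengths(d1$hyperedges), c(A = 1L, B = 1L))

  for (seed in 1:10) {
    hg <- rand_hypergraph(7, 9, 4, seed)
    dd <- dual_hypergraph(dual_hypergraph(hg))
    expect_setequal(dd$nodes, hg$nodes)
    key <- function(h) sort(vapply(h$hyperedges,
                                   function(e) paste(sort(e), collapse = ","),
                                   character(1)))
    expect_equal(key(dd), key(hg))
    # statistic panel swaps (|V|, |E|) and (Avg.d, Avg.|e|) exactly
    s <- network_stats(hg); sd <- network_stats(dual_hypergraph(hg))
    expect_equal(sd$n_nodes, s$n_edges)
    expect_equal(sd$n_edges, s$n_nodes)
    expect_equal(sd$avg_degree, s$avg_edge_size)
    expect_equal(sd$avg_edge_size, s$avg_degree)
  }
})

test_that("clique expansion matches a brute-force common-neighbour scan", {
  hg <- hypergraph(c("A", "B", "C"), list(e1 = c("A", "B", "C")))
  ce <- clique_expansion(hg, "binary")
  expect_equal(nrow(ce$edges), 3L)
  expect_true(all(ce$edges$weight == 1))

  hg2 <- hypergraph(c("A", "B"), list(e1 = c("A", "B"), e2 = c("A", "B")))
  ce2 <- clique_expansion(hg2, "shared_count")
  expect_equal(ce2$edges$weight, 2)

  for (seed in 1:8) {
    bip <- rand_bipartite(sample(3:30, 1), sample(3:30, 1), 0.25, seed)
    ce <- clique_expansion(project_hypergraph(bip, "muscle"), "shared_count")
    oracle <- brute_projection(bip)
    got <- ce$edges[order(ce$edges$u, ce$edges$v), ]
    if (is.null(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      key <- function(d) paste(pmin(d$u, d$v), pmax(d$u, d$v), d$weight)
      expect_setequal(key(got), key(oracle))
    }
  }
})

test_that("hyper-degrees and filtered degrees follow the incidence matrix", {
  hg <- fixture_mbm()
  expect_equal(hyper_degree(hg, "D"), c(6L, 5L, 4L))
  expect_error(hyper_degree(hg, "nope"), "unknown node")

  hg_iso <- hypergraph(c("A", "B", "Z"), list(e1 = c("A", "B")))
  expect_equal(hyper_degree(hg_iso, "Z"), integer(0))

  # total hyper-degree mass equals total incidence count
  for (seed in 1:6) {
    h <- rand_hypergraph(8, 10, 5, seed)
    hd_total <- sum(vapply(h$nodes, function(v) length(hyper_degree(h, v)),
                           integer(1)))
    expect_equal(hd_total, sum(lengths(h$hyperedges)))
  }

  # filtered degree: d(v) at s_min = 1, monotone non-increasing, 0 past max
  smax <- max(lengths(hg$hyperedges))
  for (v in hg$nodes) {
    fd <- vapply(1:(smax + 1), function(s) filtered_degree(hg, v, s),
                 integer(1))
    expect_equal(fd[1], length(hyper_degree(hg, v)))
    expect_true(all(diff(fd) <= 0))
    expect_equal(fd[smax + 1], 0L)
  }
})

test_that("statistic panel obeys incidence conservation and density conventions", {
  for (seed in 1:6) {
    hg <- rand_hypergraph(10, 14, 4, seed)
    s <- network_stats(hg)
    expect_equal(s$n_nodes * s$avg_degree, s$n_edges * s$avg_edge_size)
    expect_equal(s$density, s$n_edges / s$n_nodes)
    expect_lte(s$largest_cc, s$n_nodes)
    expect_gte(s$n_components, 1L)
  }
  pg <- rand_graph(20, 30, seed = 3)
  sp <- network_stats(pg)
  expect_equal(sp$avg_edge_size, 2)
  expect_equal(sp$density, 2 * 30 / (20 * 19))
  expect_equal(sp$avg_degree, 3)
})

test_that("two-mode graphs have global clustering exactly zero", {
  for (seed in 1:5) {
    bip <- rand_bipartite(6, 9, 0.3, seed)
    nodes <- c(bip$muscles, bip$bones)
    pg <- pairwise_graph(nodes, data.frame(u = bip$edges$muscle,
                                           v = bip$edges$bone))
    expect_identical(network_stats(pg)$gcc, 0)
  }
})

test_that("weighted adjacency matrices follow their schemes", {
  hg <- fixture_mbm()
  W1 <- weighted_adjacency(hg, "neighbor_degree")
  expect_true(all(diag(W1) == 0))
  W2 <- weighted_adjacency(hg, "shared_count")
  expect_identical(W2, t(W2))
  expect_equal(unname(diag(W2)),
               unname(vapply(hg$nodes,
                             function(v) length(hyper_degree(hg, v)),
                             integer(1)) * 1.0))
  ce <- clique_expansion(hg, "shared_count")
  for (i in seq_len(nrow(ce$edges)))
    expect_equal(W2[ce$edges$u[i], ce$edges$v[i]], ce$edges$weight[i])
  # every positive off-diagonal is an edge and vice versa
  offdiag <- W2; diag(offdiag) <- 0
  expect_equal(sum(offdiag > 0) / 2, nrow(ce$edges))
})

test_that("readers and writers round-trip edge lists and hyperedge lists", {
  bip <- rand_bipartite(5, 8, 0.4, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_bipartite(bip, tf)
  back <- read_bipartite(tf)
  expect_setequal(paste(back$edges$muscle, back$edges$bone),
                  paste(bip$edges$muscle, bip$edges$bone))

  # csv, comments, duplicate collapse, malformed row error with line number
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "m1,b1", "m1,b1", "m2,b2"), tf2)
  b2 <- read_bipartite(tf2)
  expect_equal(nrow(b2$edges), 2L)
  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("m1,b1", "broken"), tf3)
  expect_error(read_bipartite(tf3), "line 2")
  expect_message(load_nanatex(tf2), "2 interactions")

  hg <- fixture_mbm()
  tf4 <- withr::local_tempfile(fileext = ".txt")
  write_hyperedges(hg, tf4)
  hg2 <- read_hyperedges(tf4)
  expect_setequal(hg2$nodes, hg$nodes)
  expect_equal(lapply(hg2$hyperedges, sort)[names(hg$hyperedges)],
               lapply(hg$hyperedges, sort))

  s <- network_stats(hg)
  tf5 <- withr::local_tempfile(fileext = ".tsv")
  write_stats(list(MbM = s), tf5)
  tab <- read.delim(tf5, check.names = FALSE)
  expect_equal(tab[["|V|"]], s$n_nodes)
  expect_equal(tab$GCC, round(s$gcc, 2))
})

test_that("muscle subsetting keeps only bones of kept muscles", {
  bip <- rand_bipartite(6, 10, 0.3, seed = 4)
  expect_error(subset_muscles(bip, c("M01", "ghost")), "ghost")
  all_back <- subset_muscles(bip, bip$muscles)
  expect_equal(all_back$edges, bip$edges)
  one <- subset_muscles(bip, "M01")
  expect_setequal(one$bones, bip$edges$bone[bip$edges$muscle == "M01"])
})
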