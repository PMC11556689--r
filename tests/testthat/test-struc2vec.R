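test_that("degree-ratio distance evaluates and is symmetric", {
  expect_equal(d0_pair(5, 5), 0)
  expect_equal(d0_pair(6, 3), 1)
  for (a in 1:20) for (b in 1:20)
    expect_equal(d0_pair(a, b), d0_pair(b, a))
  expect_error(d0_pair(0, 3), "positive")
})

test_that("DTW matches the exhaustive-alignment oracle", {
  expect_equal(dtw(c(3, 1), 2), 2)
  expect_equal(dtw(1:4, 1:4), 0)
  set.seed(101)
  for (i in 1:60) {
    a <- sample(1:9, sample.int(6, 1), replace = TRUE)
    b <- sample(1:9, sample.int(6, 1), replace = TRUE)
    expect_equal(dtw(a, b), dtw_oracle(a, b))
    expect_equal(dtw(a, b, d0_pair), dtw_oracle(a, b, d0_pair))
  }
  expect_error(dtw(numeric(0), 1), "non-empty")
})

test_that("structural distances: base cases, symmetry, monotone layers", {
  # 4-node path: endpoints share degree 1
  path <- pairwise_graph(letters[1:4],
                         data.frame(u = letters[1:3], v = letters[2:4]))
  tab <- structural_distances(path, k_max = 3)
  expect_equal(tab$D[[1]]["a", "d"], 0)

  # isomorphic components give zero distance at every layer where the
  # pair is present (it leaves a layer once its rings are exhausted)
  pg <- twin_lollipops()
  tab2 <- structural_distances(pg)
  for (k in 0:tab2$k_max)
    for (v in letters[1:5]) {
      d <- tab2$D[[k + 1]][paste0("x", v), paste0("y", v)]
      if (!is.na(d)) expect_equal(d, 0)
    }
  for (v in letters[1:5])
    expect_equal(tab2$D[[2]][paste0("x", v), paste0("y", v)], 0)

  for (seed in 1:15) {
    g <- rand_graph(sample(5:25, 1), sample(6:40, 1), seed)
    tb <- suppressWarnings(structural_distances(g, k_max = 3))
    for (k in 0:tb$k_max) {
      M <- tb$D[[k + 1]]
      expect_identical(M, t(M))
      expect_true(all(diag(M) == 0))
      if (k > 0) {
        prev <- tb$D[[k]]
        ok <- !is.na(M) & !is.na(prev)
        expect_true(all(M[ok] >= prev[ok] - 1e-12))
      }
    }
  }
})

test_that("multilayer context graph weights follow exp(-D) and the up-rule", {
  pg <- twin_lollipops()
  tab <- structural_distances(pg)
  ml <- build_multilayer(tab)
  for (k in 0:ml$k_max) {
    W <- ml$w[[k + 1]]
    D <- tab$D[[k + 1]]
    off <- upper.tri(W)
    expect_true(all(W[off] > 0 & W[off] <= 1, na.rm = TRUE))
    expect_equal(W[off][!is.na(W[off])], exp(-D[off][!is.na(D[off])]))
    # w = 1 exactly where D = 0
    expect_identical(which(W[off] == 1), which(D[off] == 0))
  }
  # a node with no above-average edges gets up-weight log(e) = 1
  iso_tab <- structural_distances(
    pairwise_graph(c("a", "b", "c", "d"),
                   data.frame(u = c("a", "c"), v = c("b", "d"))), k_max = 0)
  iso_ml <- build_multilayer(iso_tab)
  expect_true(all(iso_ml$up[, 1] == 1))  # all-equal weights: none above mean
})

test_that("multilayer walks stay on base labels and are seed-deterministic", {
  pg <- twin_lollipops()
  ml <- build_multilayer(structural_distances(pg))
  co <- multilayer_walks(ml, walks_per_node = 2, walk_length = 20, seed = 5)
  expect_length(co$walks, 10 * 2)
  expect_true(all(unlist(co$walks) %in% pg$nodes))
  co2 <- multilayer_walks(ml, walks_per_node = 2, walk_length = 20, seed = 5)
  expect_identical(co$walks, co2$walks)
})

test_that("struc2vec recovers structural twins across disjoint components", {
  expect_equal(dim(embed_struc2vec(twin_lollipops(), dim = 16, seed = 1)),
               c(10L, 16L))
  # duplicated body-plan clique expansion: the planted spanning muscles
  # have distinctive roles, so each copy should find its twin
  syn <- generate_bipartite(body_plan(seed = 11))
  pg <- clique_expansion(
    duplicate_hypergraph(project_hypergraph(syn$network, "muscle")),
    "binary")
  span <- names(which(syn$spanning))
  hits <- 0L
  for (s in 1:5) {
    D <- euclidean_distances(standardize(embed_struc2vec(pg, seed = s)))
    ok <- TRUE
    for (sp in span) {
      tw <- paste0(sp, ".2")
      ok <- ok && nearest_neighbour(D, sp) == tw &&
        nearest_neighbour(D, tw) == sp
    }
    hits <- hits + ok
  }
  expect_gte(hits, 3L)
})

test_that("barbell hubs are mutual nearest neighbours in embedding space", {
  # two triangles joined by a 3-edge path; hubs are the path endpoints
  edges <- data.frame(
    u = c("a1", "a1", "a2", "h1", "m1", "m2", "h2", "h2", "b1"),
    v = c("a2", "h1", "h1", "m1", "m2", "h2", "b1", "b2", "b2"))
  pg <- pairwise_graph(c("a1", "a2", "h1", "m1", "m2", "h2", "b1", "b2"),
                       edges)
  hits <- 0L
  for (s in 1:5) {
    D <- euclidean_distances(standardize(embed_struc2vec(pg, seed = s)))
    hits <- hits + (nearest_neighbour(D, "h1") == "h2" &&
                      nearest_neighbour(D, "h2") == "h1")
  }
  expect_gte(hits, 3L)
})

test_that("distance tables export in long format", {
  pg <- twin_lollipops()
  tab <- structural_distances(pg, k_max = 2)
  tf <- withr::local_tempfile()
  write_distance_table(tab, tf)
  long <- read.delim(tf)
  expect_named(long, c("u", "v", "k", "D_k"))
  i <- which(long$u == "xa" & long$v == "ya" & long$k == 2)
  expect_equal(long$D_k[i], 0)
})
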