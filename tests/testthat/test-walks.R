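test_that("uniform walks respect adjacency and corpus bookkeeping", {
  pg <- pairwise_graph(c("A", "B"), data.frame(u = "A", v = "B"))
  co <- uniform_walks(pg, walks_per_node = 2, walk_length = 9, seed = 1)
  expect_length(co$walks, 2 * 2)
  for (w in co$walks) {
    expect_length(w, 9L)
    expect_true(all(w == rep(c(w[1], setdiff(c("A", "B"), w[1])),
                             length.out = 9)))
  }

  pg2 <- rand_graph(12, 20, seed = 5)
  edge_keys <- with(pg2$edges, c(paste(u, v), paste(v, u)))
  co2 <- uniform_walks(pg2, walks_per_node = 3, walk_length = 15, seed = 2)
  expect_length(co2$walks, 12 * 3)
  steps <- unlist(lapply(co2$walks, function(w)
    if (length(w) > 1) paste(w[-length(w)], w[-1])))
  expect_true(all(steps %in% edge_keys))

  # isolated node emits the singleton walk
  pg3 <- pairwise_graph(c("A", "B", "Z"), data.frame(u = "A", v = "B"))
  co3 <- uniform_walks(pg3, walks_per_node = 1, walk_length = 5, seed = 1)
  expect_identical(co3$walks[[3]], "Z")

  expect_identical(uniform_walks(pg2, 3, 15, seed = 9)$walks,
                   uniform_walks(pg2, 3, 15, seed = 9)$walks)
})

test_that("hub transitions of a star are uniform over the leaves", {
  pg <- pairwise_graph(c("H", "L1", "L2", "L3"),
                       data.frame(u = "H", v = c("L1", "L2", "L3")))
  co <- uniform_walks(pg, walks_per_node = 1, walk_length = 1e5, seed = 42)
  w <- co$walks[[1]]
  leaves <- w[seq(2, length(w), by = 2)]  # walk alternates hub, leaf
  tab <- table(factor(leaves, levels = c("L1", "L2", "L3")))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("biased walks interpolate between return and exploration", {
  # p = q = 1 on a triangle: uniform over the two neighbours
  tri <- pairwise_graph(c("A", "B", "C"),
                        data.frame(u = c("A", "B", "C"),
                                   v = c("B", "C", "A")))
  co <- biased_walks(tri, p = 1, q = 1, walks_per_node = 2,
                     walk_length = 3000, seed = 1)
  steps <- unlist(lapply(co$walks, function(w)
    w[-1][w[-length(w)] == "A"]))
  frac <- mean(steps == "B")
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)

  # huge q on a path suppresses outward moves
  path <- pairwise_graph(letters[1:6],
                         data.frame(u = letters[1:5], v = letters[2:6]))
  co2 <- biased_walks(path, p = 1, q = 1e6, walks_per_node = 2,
                      walk_length = 200, seed = 3)
  outward <- 0; chances <- 0
  for (w in co2$walks) {
    for (i in seq_len(length(w) - 2)) {
      t <- w[i]; v <- w[i + 1]; x <- w[i + 2]
      if (v %in% c("a", "f")) next      # endpoint: forced return
      chances <- chances + 1
      if (x != t) outward <- outward + 1
    }
  }
  expect_lt(outward / chances, 0.02)

  expect_identical(biased_walks(path, 2, 0.5, 2, 30, seed = 4)$walks,
                   biased_walks(path, 2, 0.5, 2, 30, seed = 4)$walks)
  expect_error(biased_walks(path, p = 0, q = 1), "positive")
})

test_that("skip-gram separates locally coherent corpora under both objectives", {
  pg <- pairwise_graph(c("A", "B", "C", "D"),
                       data.frame(u = c("A", "C"), v = c("B", "D")))
  for (obj in c("negative_sampling", "hierarchical_softmax")) {
    within <- numeric(0); across <- numeric(0)
    for (s in 1:5) {
      co <- uniform_walks(pg, walks_per_node = 10, walk_length = 40, seed = s)
      emb <- train_skipgram(co, dim = 8, objective = obj, seed = s,
                            nodes = pg$nodes)
      expect_equal(dim(emb), c(4L, 8L))
      cs <- function(a, b) sum(emb[a, ] * emb[b, ]) /
        sqrt(sum(emb[a, ]^2) * sum(emb[b, ]^2))
      within <- c(within, cs("A", "B"), cs("C", "D"))
      across <- c(across, cs("A", "C"), cs("B", "D"))
    }
    expect_gt(mean(within), mean(across))
  }
})

test_that("skip-gram output shape, determinism, and error contracts hold", {
  pg <- rand_graph(10, 18, seed = 1)
  co <- uniform_walks(pg, 5, 30, seed = 1)
  emb <- train_skipgram(co, dim = 16, seed = 2, nodes = pg$nodes)
  expect_equal(dim(emb), c(10L, 16L))
  emb2 <- train_skipgram(co, dim = 16, seed = 2, nodes = pg$nodes)
  expect_identical(unclass(emb), unclass(emb2))

  expect_error(train_skipgram(co, nodes = c(pg$nodes, "ghost")), "ghost")
  empty <- co; empty$walks <- list()
  expect_error(train_skipgram(empty), "empty corpus")
})

test_that("corpus and embedding files round-trip", {
  pg <- rand_graph(6, 8, seed = 2)
  co <- uniform_walks(pg, 2, 10, seed = 1)
  tf <- withr::local_tempfile()
  write_corpus(co, tf)
  expect_identical(read_corpus(tf)$walks, co$walks)
  emb <- train_skipgram(co, dim = 4, seed = 1)
  tf2 <- withr::local_tempfile()
  write_embedding(emb, tf2)
  back <- read.delim(tf2)
  expect_equal(as.matrix(back[, -1]), unclass(emb), ignore_attr = TRUE,
               tolerance = 1e-6)
})
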