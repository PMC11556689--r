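#' @useDynLib hypermsk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.adjlist <- function(g) {
  if (inherits(g, "hypergraph")) g <- clique_expansion(g, "binary")
  stopifnot(inherits(g, "pairwise_graph"))
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in g$nodes) adj[[v]] <- character(0)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      u <- g$edges$u[i]; v <- g$edges$v[i]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

.walk_corpus <- function(walks, walk_length, walks_per_node, seed) {
  structure(list(walks = walks, walk_length = walk_length,
                 walks_per_node = walks_per_node, seed = seed),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat("<walk_corpus> ", length(x$walks), " walks, length ",
      x$walk_length, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Uniform random walks on a pairwise graph
#'
#' The DeepWalk corpus generator: from every node, `walks_per_node`
#' walks of `walk_length` nodes each, sampling the next node uniformly
#' from the neighbours of the current one. A degree-zero node emits the
#' singleton walk `[v]`. Reproducible for a fixed seed.
#'
#' @param g a [pairwise_graph()] (or a [hypergraph()], which is
#'   clique-expanded first).
#' @param walks_per_node walks started from each node.
#' @param walk_length number of nodes per walk.
#' @param seed integer RNG seed.
#' @return a `walk_corpus` (list of node-label sequences).
#' @export
uniform_walks <- function(g, walks_per_node = 10L, walk_length = 80L,
                          seed = 1L) {
  adj <- .adjlist(g)
  if (!length(adj)) stop("empty graph")
  stopifnot(walk_length >= 1L, walks_per_node >= 1L)
  set.seed(seed)
  walks <- vector("list", length(adj) * walks_per_node)
  w <- 0L
  for (v in names(adj)) {
    for (r in seq_len(walks_per_node)) {
      walk <- character(walk_length)
      walk[1L] <- v
      cur <- v
      len <- 1L
      while (len < walk_length) {
        nbr <- adj[[cur]]
        if (!length(nbr)) break
        cur <- nbr[sample.int(length(nbr), 1L)]
        len <- len + 1L
        walk[len] <- cur
      }
      w <- w + 1L
      walks[[w]] <- walk[seq_len(len)]
    }
  }
  .walk_corpus(walks, walk_length, walks_per_node, seed)
}

#' Second-order biased random walks (node2vec)
#'
#' Biased walk interpolating between breadth-first and depth-first
#' exploration. Given the previous node t and current node v, the
#' unnormalised weight of moving to neighbour x is 1/p if x = t
#' (return), 1 if x is a common neighbour of t and v, and 1/q
#' otherwise. With p = q = 1 the walk reduces to [uniform_walks()] in
#' distribution.
#'
#' @inheritParams uniform_walks
#' @param p return parameter, > 0.
#' @param q in-out parameter, > 0.
#' @return a `walk_corpus`.
#' @export
biased_walks <- function(g, p = 1, q = 1, walks_per_node = 10L,
                         walk_length = 80L, seed = 1L) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  adj <- .adjlist(g)
  if (!length(adj)) stop("empty graph")
  stopifnot(walk_length >= 1L, walks_per_node >= 1L)
  set.seed(seed)
  walks <- vector("list", length(adj) * walks_per_node)
  w <- 0L
  for (v in names(adj)) {
    for (r in seq_len(walks_per_node)) {
      walk <- character(walk_length)
      walk[1L] <- v
      len <- 1L
      prev <- NA_character_
      cur <- v
      while (len < walk_length) {
        nbr <- adj[[cur]]
        if (!length(nbr)) break
        if (is.na(prev)) {
          nxt <- nbr[sample.int(length(nbr), 1L)]
        } else {
          wgt <- ifelse(nbr == prev, 1 / p,
                        ifelse(nbr %in% adj[[prev]], 1, 1 / q))
          nxt <- nbr[sample.int(length(nbr), 1L, prob = wgt)]
        }
        prev <- cur
        cur <- nxt
        len <- len + 1L
        walk[len] <- cur
      }
      w <- w + 1L
      walks[[w]] <- walk[seq_len(len)]
    }
  }
  .walk_corpus(walks, walk_length, walks_per_node, seed)
}

#' Train skip-gram node embeddings from a walk corpus
#'
#' word2vec-style skip-gram over random-walk "sentences": for every
#' node occurrence the model maximises the probability of the nodes in
#' a window around it, via negative sampling (default, 5 noise nodes
#' drawn from the unigram^0.75 distribution) or hierarchical softmax
#' over a Huffman tree of corpus frequencies. Training is
#' single-threaded and uses R's RNG, so results are bitwise
#' reproducible for a fixed seed.
#'
#' @param corpus a `walk_corpus`.
#' @param dim embedding dimension d.
#' @param window context radius w.
#' @param epochs passes over the corpus.
#' @param objective `"negative_sampling"` or `"hierarchical_softmax"`.
#' @param negative number of noise samples (negative sampling only).
#' @param alpha initial learning rate.
#' @param seed integer RNG seed.
#' @param nodes optional character vector of required node labels; an
#'   error lists any of them missing from the corpus, and the output
#'   rows follow this order.
#' @return an `embedding_matrix`: a numeric node-by-d matrix with
#'   rownames and attributes `standardized` (FALSE), `method`, `seed`.
#' @export
train_skipgram <- function(corpus, dim = 16L, window = 5L, epochs = 5L,
                           objective = c("negative_sampling",
                                         "hierarchical_softmax"),
                           negative = 5L, alpha = 0.025, seed = 1L,
                           nodes = NULL) {
  stopifnot(inherits(corpus, "walk_corpus"), dim >= 1L, window >= 1L,
            epochs >= 1L)
  objective <- match.arg(objective)
  if (!length(corpus$walks)) stop("empty corpus")
  vocab <- unique(unlist(corpus$walks, use.names = FALSE))
  if (!length(vocab)) stop("empty corpus")
  if (!is.null(nodes)) {
    if (length(missing <- setdiff(nodes, vocab)))
      stop("nodes absent from corpus: ", paste(missing, collapse = ", "))
    vocab <- c(nodes, setdiff(vocab, nodes))
  }
  iwalks <- lapply(corpus$walks, function(w) match(w, vocab))
  set.seed(seed)
  M <- .skipgram_train(iwalks, length(vocab), as.integer(dim),
                       as.integer(window), as.integer(epochs),
                       as.integer(negative),
                       if (objective == "negative_sampling") 0L else 1L,
                       alpha)
  rownames(M) <- vocab
  if (!is.null(nodes)) M <- M[nodes, , drop = FALSE]
  embedding_matrix(M, method = "skipgram", seed = seed)
}

#' Construct an embedding matrix
#'
#' @param m numeric matrix with node labels as rownames.
#' @param method provenance tag.
#' @param seed RNG seed used, if any.
#' @param standardized whether columns are already z-scored.
#' @return an `embedding_matrix`.
#' @export
embedding_matrix <- function(m, method = "unknown", seed = NA_integer_,
                             standardized = FALSE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (any(!is.finite(m))) stop("embedding contains non-finite entries")
  structure(m, class = c("embedding_matrix", class(m)),
            method = method, seed = seed, standardized = standardized)
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", nrow(x), " nodes x ", ncol(x),
      " dims, method=", attr(x, "method"),
      if (isTRUE(attr(x, "standardized"))) ", standardized" else "",
      "\n", sep = "")
  invisible(x)
}

#' Serialize / read a walk corpus (one walk per line)
#'
#' @param corpus a `walk_corpus`.
#' @param path file path.
#' @return `path` (write) or a `walk_corpus` (read).
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "walk_corpus"))
  writeLines(vapply(corpus$walks, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  walks <- strsplit(readLines(path, encoding = "UTF-8"), " ", fixed = TRUE)
  .walk_corpus(walks, max(lengths(walks)), NA_integer_, NA_integer_)
}

#' Write an embedding matrix as TSV (label + d floats)
#'
#' @param emb an `embedding_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(node = rownames(emb), unclass(emb)[, , drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' DeepWalk embedding of a pairwise graph
#'
#' Uniform random walks + skip-gram, the proximity-based baseline.
#'
#' @inheritParams uniform_walks
#' @inheritParams train_skipgram
#' @return an `embedding_matrix` (|V| x dim).
#' @export
embed_deepwalk <- function(g, dim = 16L, walks_per_node = 10L,
                           walk_length = 80L, window = 5L, epochs = 5L,
                           objective = "negative_sampling", seed = 1L) {
  if (inherits(g, "hypergraph")) g <- clique_expansion(g, "binary")
  corpus <- uniform_walks(g, walks_per_node, walk_length, seed)
  emb <- train_skipgram(corpus, dim, window, epochs, objective, seed = seed,
                        nodes = g$nodes)
  attr(emb, "method") <- "deepwalk"
  emb
}

#' node2vec embedding of a pairwise graph
#'
#' Biased second-order walks + skip-gram.
#'
#' @inheritParams biased_walks
#' @inheritParams train_skipgram
#' @return an `embedding_matrix` (|V| x dim).
#' @export
embed_node2vec <- function(g, dim = 16L, p = 1, q = 1, walks_per_node = 10L,
                           walk_length = 80L, window = 5L, epochs = 5L,
                           objective = "negative_sampling", seed = 1L) {
  if (inherits(g, "hypergraph")) g <- clique_expansion(g, "binary")
  corpus <- biased_walks(g, p, q, walks_per_node, walk_length, seed)
  emb <- train_skipgram(corpus, dim, window, epochs, objective, seed = seed,
                        nodes = g$nodes)
  attr(emb, "method") <- "node2vec"
  emb
}
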