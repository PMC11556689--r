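#' Standardize an embedding matrix
#'
#' Z-scores every embedding dimension across nodes (mean 0, sd 1) so
#' that Euclidean distances weight all dimensions equally;
#' zero-variance dimensions become all-zero columns rather than NaN.
#' `"minmax"` rescales each dimension to \[0, 1\] instead, offered as
#' an alternative convention.
#'
#' @param emb an `embedding_matrix` with at least two nodes.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return the standardized `embedding_matrix` (idempotent for
#'   `"zscore"`).
#' @export
standardize <- function(emb, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  stopifnot(is.matrix(emb))
  if (nrow(emb) < 2L) stop("standardization needs at least two nodes")
  m <- unclass(emb)
  if (method == "zscore") {
    mu <- colMeans(m)
    sdv <- apply(m, 2L, stats::sd)
    m <- sweep(m, 2L, mu, "-")
    pos <- sdv > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2L, sdv[pos], "/")
    m[, !pos] <- 0
  } else {
    rng <- apply(m, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    m <- sweep(m, 2L, rng[1L, ], "-")
    pos <- span > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2L, span[pos], "/")
    m[, !pos] <- 0
  }
  embedding_matrix(m, method = attr(emb, "method") %||% "unknown",
                   seed = attr(emb, "seed") %||% NA_integer_,
                   standardized = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Euclidean distance matrix of an embedding
#'
#' @param emb an `embedding_matrix`; a warning is emitted if it has not
#'   been [standardize()]d, since raw dimensions are not comparable
#'   across methods.
#' @return a `distance_matrix`: symmetric nonnegative matrix with zero
#'   diagonal and provenance attributes (`method`, `seed`).
#' @export
euclidean_distances <- function(emb) {
  stopifnot(is.matrix(emb))
  if (any(is.na(emb))) stop("embedding contains NA/NaN entries")
  if (!isTRUE(attr(emb, "standardized")))
    warning("embedding is not standardized; distances mix raw scales")
  D <- as.matrix(stats::dist(unclass(emb)))
  structure(D, class = c("distance_matrix", class(D)),
            method = attr(emb, "method"), seed = attr(emb, "seed"))
}

#' Distance profiles of target muscles
#'
#' For each target node, the distance to every node in the fixed node
#' order of the matrix (including the targets themselves), annotated
#' with body parts - the per-muscle bar profile used to compare
#' embedding methods.
#'
#' @param dist a `distance_matrix` from [euclidean_distances()].
#' @param targets character vector of target node labels.
#' @param parts optional named character vector of body-part labels.
#' @return named list of data frames (`node`, `distance`, `part`), one
#'   per target; class `target_profiles`.
#' @export
target_profiles <- function(dist, targets, parts = NULL) {
  stopifnot(is.matrix(dist))
  nodes <- rownames(dist)
  if (length(missing <- setdiff(targets, nodes)))
    stop("unknown target: ", paste(missing, collapse = ", "))
  out <- lapply(stats::setNames(targets, targets), function(tg)
    data.frame(node = nodes,
               distance = as.numeric(dist[tg, nodes]),
               part = if (is.null(parts)) NA_character_
                      else as.character(parts[nodes]),
               stringsAsFactors = FALSE))
  structure(out, class = "target_profiles")
}

#' Spanning-muscle separation score
#'
#' A scalar summary of how distinctly an embedding isolates the
#' spanning muscles: the mean distance from each spanning node to the
#' non-spanning nodes of its own body part, minus the mean distance
#' between the spanning nodes themselves. Higher scores mean the
#' spanning muscles look mutually similar yet stand apart from their
#' part-mates. This score is a summary statistic introduced by this
#' package to make the visual method comparison quantitative; it is
#' not a published quantity.
#'
#' @param dist a `distance_matrix`.
#' @param spanning character vector of spanning node labels.
#' @param parts named character vector of body-part labels per node.
#' @return an object of class `separation_report`: list with `score`,
#'   `mean_to_part_mates`, `mean_between_spanning`, `per_target`
#'   (named numeric), `method`.
#' @export
spanning_separation <- function(dist, spanning, parts) {
  stopifnot(is.matrix(dist))
  nodes <- rownames(dist)
  spanning <- intersect(nodes, spanning)
  others <- setdiff(nodes, spanning)
  if (!length(spanning) || !length(others))
    stop("need at least one spanning and one non-spanning node")
  per_target <- vapply(spanning, function(s) {
    mates <- others[parts[others] == parts[[s]]]
    if (!length(mates))
      stop("spanning node ", s, " has no non-spanning part-mates")
    mean(dist[s, mates])
  }, numeric(1))
  mean_to_mates <- mean(per_target)
  between <- if (length(spanning) > 1L) {
    sub <- dist[spanning, spanning, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else 0
  structure(list(score = mean_to_mates - between,
                 mean_to_part_mates = mean_to_mates,
                 mean_between_spanning = between,
                 per_target = per_target,
                 method = attr(dist, "method") %||% "unknown"),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report> method=", x$method,
      "  score=", round(x$score, 4),
      "  (part-mates ", round(x$mean_to_part_mates, 4),
      " - between-spanning ", round(x$mean_between_spanning, 4), ")\n",
      "note: package-defined summary score, not a published quantity\n",
      sep = "")
  invisible(x)
}

#' Plot target distance profiles
#'
#' Bar chart per muscle, coloured by body part, one facet per target;
#' headless-safe (returns a ggplot object, draws nothing). Requires
#' ggplot2.
#'
#' @param profiles a `target_profiles` object.
#' @return a ggplot object.
#' @export
plot_profiles <- function(profiles) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_profiles() requires the ggplot2 package")
  df <- do.call(rbind, lapply(names(profiles), function(tg)
    cbind(target = tg, profiles[[tg]])))
  df$node <- factor(df$node, levels = unique(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$distance,
                                   fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~target, ncol = 1L) +
    ggplot2::labs(x = NULL, y = "Euclidean distance (standardized)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
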