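#' Normalized hypergraph Laplacian
#'
#' The standard normalized Laplacian of a hypergraph with unit
#' hyperedge weights:
#' `L = I - Dv^{-1/2} H De^{-1} H' Dv^{-1/2}`,
#' where H is the binary node-by-hyperedge incidence matrix, Dv the
#' diagonal of node degrees and De the diagonal of hyperedge sizes. L
#' is symmetric with real eigenvalues in \[0, 2\]; for a connected
#' hypergraph the degree-scaled constant vector is its only
#' 0-eigenvector, and in general the 0-eigenvalue multiplicity equals
#' the number of connected components.
#'
#' @param hg a [hypergraph()]; every node must have degree >= 1.
#' @return an object of class `hypergraph_laplacian`: list with `L`
#'   (node-by-node matrix), `d_v` (node degrees), `d_e` (hyperedge
#'   sizes).
#' @export
normalized_laplacian <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- incidence_matrix(hg)
  d_v <- rowSums(H)
  if (any(d_v == 0))
    stop("degree-zero node(s): ",
         paste(rownames(H)[d_v == 0], collapse = ", "))
  d_e <- colSums(H)
  inv_sqrt_dv <- 1 / sqrt(d_v)
  HWDe <- sweep(H, 2L, d_e, "/")           # H De^{-1}
  Theta <- outer(inv_sqrt_dv, inv_sqrt_dv) * (HWDe %*% t(H))
  L <- diag(nrow(H)) - Theta
  dimnames(L) <- list(rownames(H), rownames(H))
  L <- (L + t(L)) / 2                      # enforce exact symmetry
  structure(list(L = L, d_v = d_v, d_e = d_e),
            class = "hypergraph_laplacian")
}

#' Spectral hypergraph embedding (HHE)
#'
#' Embeds the nodes with the eigenvectors of the normalized hypergraph
#' Laplacian belonging to the `k` smallest eigenvalues above a zero
#' tolerance, sorted ascending. Near-zero eigenvalues (one per
#' connected component) are skipped. The sign of each eigenvector is
#' fixed by making its largest-magnitude entry positive, and columns
#' with numerically tied eigenvalues are ordered lexicographically, so
#' the output is deterministic.
#'
#' @param hg a [hypergraph()].
#' @param k number of embedding dimensions; must not exceed the number
#'   of nonzero eigenvalues.
#' @param tol zero-eigenvalue tolerance.
#' @return an `embedding_matrix` (|V| x k) with attribute
#'   `eigenvalues`.
#' @export
embed_hhe <- function(hg, k = 16L, tol = 1e-9) {
  lap <- normalized_laplacian(hg)
  eig <- eigen(lap$L, symmetric = TRUE)
  ord <- order(eig$values)                 # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  nonzero <- which(vals > tol)
  if (k > length(nonzero))
    stop("k = ", k, " exceeds the ", length(nonzero),
         " nonzero eigenvalues of the spectrum")
  sel <- nonzero[seq_len(k)]
  vals <- vals[sel]
  vecs <- vecs[, sel, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  # deterministic order inside numerically tied eigenvalue groups
  grp <- cumsum(c(TRUE, diff(vals) > tol))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) > 1L) {
      o <- do.call(order, as.data.frame(t(vecs[, cols, drop = FALSE])))
      vecs[, cols] <- vecs[, cols[o], drop = FALSE]
      vals[cols] <- vals[cols[o]]
    }
  }
  rownames(vecs) <- rownames(lap$L)
  emb <- embedding_matrix(vecs, method = "hhe", seed = NA_integer_)
  attr(emb, "eigenvalues") <- vals
  emb
}

#' Write the Laplacian spectrum as TSV (index, eigenvalue)
#'
#' @param hg a [hypergraph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(hg, path) {
  lap <- normalized_laplacian(hg)
  vals <- sort(eigen(lap$L, symmetric = TRUE, only.values = TRUE)$values)
  writeLines(c("index\teigenvalue",
               paste(seq_along(vals), vals, sep = "\t")), path)
  invisible(path)
}
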