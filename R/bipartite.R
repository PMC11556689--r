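#' Bipartite muscle-bone network
#'
#' Construct a bipartite network with two disjoint labelled node sets
#' (muscles and bones) and unweighted cross-edges. Labels are
#' case-sensitive, whitespace-trimmed strings; node order is
#' first-appearance order and is kept fixed for all matrix layouts
#' downstream. Duplicate edges collapse to one (incidence is binary).
#'
#' @param edges a two-column data frame (muscle, bone) or a matrix of
#'   character labels.
#' @param muscles,bones optional label vectors fixing the node order and
#'   allowing isolated nodes; defaults to first appearance in `edges`.
#' @return an object of class `bipartite_network` with fields
#'   `muscles`, `bones` and `edges` (a de-duplicated data frame).
#' @examples
#' bip <- bipartite_network(data.frame(
#'   muscle = c("A", "B"), bone = c("x", "x")))
#' bip
#' @export
bipartite_network <- function(edges, muscles = NULL, bones = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs two columns (muscle, bone)")
  m <- trimws(as.character(edges[[1L]]))
  b <- trimws(as.character(edges[[2L]]))
  keep <- !duplicated(paste(m, b, sep = "\r"))
  m <- m[keep]; b <- b[keep]
  if (any(m == "") || any(b == "")) stop("empty labels are not allowed")
  muscles <- if (is.null(muscles)) unique(m) else trimws(as.character(muscles))
  bones <- if (is.null(bones)) unique(b) else trimws(as.character(bones))
  if (anyDuplicated(muscles) || anyDuplicated(bones))
    stop("duplicate labels in a node set")
  if (length(bad <- setdiff(m, muscles)))
    stop("edge endpoint not in muscle set: ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(b, bones)))
    stop("edge endpoint not in bone set: ", paste(bad, collapse = ", "))
  if (length(common <- intersect(muscles, bones)))
    stop("labels shared between muscle and bone sets: ",
         paste(common, collapse = ", "))
  structure(
    list(muscles = muscles, bones = bones,
         edges = data.frame(muscle = m, bone = b, stringsAsFactors = FALSE)),
    class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("<bipartite_network> ", length(x$muscles), " muscles, ",
      length(x$bones), " bones, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Restrict a bipartite network to a muscle subset
#'
#' Keeps the listed muscles and only the bones attached to at least one
#' kept muscle; this is how the 18-muscle study network is carved out of
#' a full anatomical edge list.
#'
#' @param bip a [bipartite_network()].
#' @param muscle_list character vector of muscle labels to keep.
#' @return a `bipartite_network`.
#' @export
subset_muscles <- function(bip, muscle_list) {
  stopifnot(inherits(bip, "bipartite_network"))
  muscle_list <- trimws(as.character(muscle_list))
  if (!length(muscle_list)) stop("`muscle_list` must be non-empty")
  if (length(missing <- setdiff(muscle_list, bip$muscles)))
    stop("muscle not present in network: ", paste(missing, collapse = ", "))
  e <- bip$edges[bip$edges$muscle %in% muscle_list, , drop = FALSE]
  kept_bones <- bip$bones[bip$bones %in% unique(e$bone)]
  bipartite_network(e, muscles = muscle_list, bones = kept_bones)
}

#' Read a two-column muscle-bone edge list
#'
#' Accepts TSV or CSV (separator sniffed from the first data line unless
#' given), UTF-8, optional header, comment lines starting with `#`.
#' Duplicate rows collapse to a single edge.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma.
#' @param header `"auto"` drops a first row that looks like column
#'   names (e.g. `muscle`/`bone`), or `TRUE`/`FALSE`.
#' @return a [bipartite_network()].
#' @export
read_bipartite <- function(path, sep = NULL, header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data rows in ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[idx[1L]])) "\t" else ","
  rows <- strsplit(lines[idx], sep, fixed = TRUE)
  bad <- which(vapply(rows, function(r) sum(nzchar(trimws(r))) < 2L, logical(1)))
  first <- vapply(rows, function(r) trimws(r[1L]), character(1))
  second <- vapply(rows, function(r) trimws(r[2L]), character(1))
  drop_first <- isTRUE(header) ||
    (identical(header, "auto") &&
       all(tolower(c(first[1L], second[1L])) %in%
             c("muscle", "bone", "muscles", "bones", "source", "target",
               "from", "to")))
  if (length(bad)) {
    bad <- setdiff(bad, if (drop_first) 1L else integer(0))
    if (length(bad))
      stop("malformed row at line ", idx[bad[1L]], " of ", path,
           " (need two non-empty fields)")
  }
  if (drop_first) { first <- first[-1L]; second <- second[-1L] }
  if (!length(first)) stop("no data rows in ", path)
  bipartite_network(data.frame(muscle = first, bone = second,
                               stringsAsFactors = FALSE))
}

#' Write a bipartite network as a two-column TSV
#'
#' @param bip a [bipartite_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bipartite <- function(bip, path) {
  stopifnot(inherits(bip, "bipartite_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("muscle\tbone", con)
  writeLines(paste(bip$edges$muscle, bip$edges$bone, sep = "\t"), con)
  invisible(path)
}

#' Load a NAnaTex-style anatomical edge list
#'
#' Thin wrapper over [read_bipartite()] for the open Network of
#' Anatomical Texts muscle-bone interaction table; duplicates collapse
#' and the resulting counts are reported via [message()].
#'
#' @param path file path to the interaction table.
#' @return a [bipartite_network()].
#' @export
load_nanatex <- function(path) {
  bip <- read_bipartite(path)
  message(sprintf("loaded %d interactions of %d muscles and %d bones",
                  nrow(bip$edges), length(bip$muscles), length(bip$bones)))
  bip
}
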