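#' Body-plan configuration for synthetic muscle-bone networks
#'
#' Parametric description of a blocky bipartite muscle-bone network:
#' muscles are grouped into body parts, bones belong to exactly one
#' part, non-spanning muscles attach only to bones of their own part,
#' and a small set of planted spanning muscles attaches to bones in two
#' or more parts. The defaults mirror the scale of the 18-muscle
#' musculoskeletal study network: five body parts (forearm, upper arm,
#' trunk, upper leg, lower leg) holding 2/3/6/4/3 muscles, 13 bones per
#' part (65 total), a target average muscle degree of 7.44 bones per
#' muscle, and two planted spanning muscles - one bridging upper arm
#' and trunk (the deltoid's role) and one bridging upper leg and trunk
#' (the rectus femoris's role).
#'
#' @param n_parts number of body parts.
#' @param part_names part labels, length `n_parts`.
#' @param muscles_per_part,bones_per_part integer vectors, length
#'   `n_parts`, all entries >= 1.
#' @param intra_part_attachment_prob Bernoulli attachment probability
#'   per (muscle, bone-in-part); used as-is only when
#'   `target_avg_muscle_degree` is `NA`, otherwise rescaled per muscle
#'   so that the expected degree equals the target.
#' @param spanning_muscles list of `list(muscle = <global muscle
#'   index>, parts = <integer part indices>)`; each spanning muscle
#'   must reference at least two distinct parts.
#' @param target_avg_muscle_degree expected bones per muscle (`NA` to
#'   use the raw probability).
#' @param seed integer RNG seed recorded in the config and used by
#'   [generate_bipartite()].
#' @return an object of class `body_plan`.
#' @export
body_plan <- function(n_parts = 5L,
                      part_names = c("Forearm", "UpperArm", "Trunk",
                                     "UpperLeg", "LowerLeg"),
                      muscles_per_part = c(2L, 3L, 6L, 4L, 3L),
                      bones_per_part = rep(13L, 5L),
                      intra_part_attachment_prob = 0.5,
                      spanning_muscles = list(
                        list(muscle = 3L, parts = c(2L, 3L)),
                        list(muscle = 13L, parts = c(4L, 3L))),
                      target_avg_muscle_degree = 7.44,
                      seed = 1L) {
  stopifnot(n_parts >= 1L,
            length(part_names) == n_parts,
            length(muscles_per_part) == n_parts,
            length(bones_per_part) == n_parts,
            all(muscles_per_part >= 1L), all(bones_per_part >= 1L),
            intra_part_attachment_prob >= 0, intra_part_attachment_prob <= 1)
  n_muscles <- sum(muscles_per_part)
  for (sp in spanning_muscles) {
    if (length(unique(sp$parts)) < 2L)
      stop("spanning muscles must reference at least two distinct parts")
    if (sp$muscle < 1L || sp$muscle > n_muscles)
      stop("spanning muscle index out of range: ", sp$muscle)
    if (any(sp$parts < 1L | sp$parts > n_parts))
      stop("spanning muscle references an unknown part")
  }
  structure(list(n_parts = as.integer(n_parts), part_names = part_names,
                 muscles_per_part = as.integer(muscles_per_part),
                 bones_per_part = as.integer(bones_per_part),
                 intra_part_attachment_prob = intra_part_attachment_prob,
                 spanning_muscles = spanning_muscles,
                 target_avg_muscle_degree = target_avg_muscle_degree,
                 seed = as.integer(seed)),
            class = "body_plan")
}

#' Generate a synthetic bipartite muscle-bone network
#'
#' Samples a bipartite network from a [body_plan()]: each non-spanning
#' muscle attaches independently to every bone of its own part with a
#' per-muscle probability (rescaled so its expected degree hits
#' `target_avg_muscle_degree`); each spanning muscle draws from the
#' bones of all its listed parts and is guaranteed at least one bone in
#' each of them. Every muscle ends up with at least one bone; bones
#' that attracted no muscle are dropped. The planted spanning muscles
#' are, by construction, the only muscles whose bones cross a part
#' boundary. Output is reproducible bitwise for a fixed `plan$seed`.
#'
#' @param plan a [body_plan()].
#' @param seed optional override of `plan$seed`.
#' @return an object of class `synthetic_bipartite`: a list with
#'   `network` (a [bipartite_network()]), `parts` (named character,
#'   body part per muscle), `spanning` (named logical) and `plan`.
#' @examples
#' syn <- generate_bipartite(body_plan(seed = 7))
#' syn$network
#' names(which(syn$spanning))
#' @export
generate_bipartite <- function(plan, seed = NULL) {
  stopifnot(inherits(plan, "body_plan"))
  if (!is.null(seed)) plan$seed <- as.integer(seed)
  set.seed(plan$seed)
  part_of_muscle <- rep(seq_len(plan$n_parts), plan$muscles_per_part)
  muscle_names <- unlist(lapply(seq_len(plan$n_parts), function(p)
    paste0(plan$part_names[p], "_m", seq_len(plan$muscles_per_part[p]))))
  bone_part <- rep(seq_len(plan$n_parts), plan$bones_per_part)
  bone_names <- unlist(lapply(seq_len(plan$n_parts), function(p)
    paste0(plan$part_names[p], "_b", seq_len(plan$bones_per_part[p]))))
  span_idx <- vapply(plan$spanning_muscles, function(sp) as.integer(sp$muscle),
                     integer(1))
  span_parts <- lapply(plan$spanning_muscles, function(sp) as.integer(sp$parts))

  edges_m <- character(0); edges_b <- character(0)
  for (i in seq_along(muscle_names)) {
    k <- match(i, span_idx)
    pool_parts <- if (!is.na(k)) span_parts[[k]] else part_of_muscle[i]
    pool <- which(bone_part %in% pool_parts)
    if (!length(pool))
      stop("muscle ", muscle_names[i], " has no candidate bones; ",
           "the configuration cannot give every muscle a bone")
    p <- if (is.na(plan$target_avg_muscle_degree))
      plan$intra_part_attachment_prob
    else plan$target_avg_muscle_degree / length(pool)
    if (p <= 0)
      stop("attachment probability is zero for muscle ", muscle_names[i],
           "; the configuration cannot give every muscle a bone")
    if (p > 1) {
      warning("target degree exceeds the bone pool for ", muscle_names[i],
              "; attaching to every candidate bone")
      p <- 1
    }
    attached <- pool[stats::runif(length(pool)) < p]
    if (!is.na(k)) {
      # guarantee >= 1 bone in every listed part
      for (pp in span_parts[[k]]) {
        in_pp <- which(bone_part[attached] == pp)
        if (!length(in_pp)) {
          cand <- pool[bone_part[pool] == pp]
          attached <- c(attached, cand[sample.int(length(cand), 1L)])
        }
      }
      attached <- sort(unique(attached))
    } else if (!length(attached)) {
      attached <- pool[sample.int(length(pool), 1L)]
    }
    edges_m <- c(edges_m, rep(muscle_names[i], length(attached)))
    edges_b <- c(edges_b, bone_names[attached])
  }
  kept_bones <- bone_names[bone_names %in% unique(edges_b)]
  net <- bipartite_network(
    data.frame(muscle = edges_m, bone = edges_b, stringsAsFactors = FALSE),
    muscles = muscle_names, bones = kept_bones)
  spanning <- stats::setNames(seq_along(muscle_names) %in% span_idx,
                              muscle_names)
  parts <- stats::setNames(plan$part_names[part_of_muscle], muscle_names)
  structure(list(network = net, parts = parts, spanning = spanning,
                 plan = plan),
            class = "synthetic_bipartite")
}

#' @export
print.synthetic_bipartite <- function(x, ...) {
  cat("<synthetic_bipartite> seed=", x$plan$seed, "; ", sep = "")
  print(x$network)
  invisible(x)
}

#' Write the sidecar annotation of a synthetic network
#'
#' TSV with columns `muscle`, `part`, `is_spanning` so that downstream
#' evaluation can recover the planted structure.
#'
#' @param syn a `synthetic_bipartite` from [generate_bipartite()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(syn, path) {
  stopifnot(inherits(syn, "synthetic_bipartite"))
  writeLines(c("muscle\tpart\tis_spanning",
               paste(names(syn$parts), syn$parts,
                     ifelse(syn$spanning, "1", "0"), sep = "\t")), path)
  invisible(path)
}

#' Write a body plan as a flat key-value file
#'
#' @param plan a [body_plan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_body_plan <- function(plan, path) {
  stopifnot(inherits(plan, "body_plan"))
  span <- vapply(plan$spanning_muscles, function(sp)
    paste0(sp$muscle, ":", paste(sp$parts, collapse = "+")), character(1))
  writeLines(c(
    paste0("n_parts=", plan$n_parts),
    paste0("part_names=", paste(plan$part_names, collapse = ",")),
    paste0("muscles_per_part=", paste(plan$muscles_per_part, collapse = ",")),
    paste0("bones_per_part=", paste(plan$bones_per_part, collapse = ",")),
    paste0("intra_part_attachment_prob=", plan$intra_part_attachment_prob),
    paste0("spanning_muscles=", paste(span, collapse = ";")),
    paste0("target_avg_muscle_degree=", plan$target_avg_muscle_degree),
    paste0("seed=", plan$seed)), path)
  invisible(path)
}

#' Hand-written toy musculoskeletal hypergraph
#'
#' A small synthetic muscle-centric hypergraph used in unit tests and
#' examples: eight muscles in two body parts, six bones (hyperedges),
#' and one planted spanning muscle `"D"` that bridges both parts. `"D"`
#' sits in three bones of sizes 6, 5 and 4, mimicking the attachment
#' pattern of a shoulder-girdle muscle. Part labels and the spanning
#' flag ride along as `parts` and `spanning` fields.
#'
#' @return a [hypergraph()] with `parts` and `spanning` set.
#' @examples
#' hg <- fixture_mbm()
#' hyper_degree(hg, "D")
#' @export
fixture_mbm <- function() {
  he <- list(
    b1 = c("D", "m1", "m2", "m3", "m4", "m5"),
    b2 = c("D", "m4", "m5", "m6", "m7"),
    b3 = c("D", "m1", "m2", "m3"),
    b4 = c("m1", "m2"),
    b5 = c("m6", "m7"),
    b6 = c("m4", "m6", "m7"))
  nodes <- c("D", paste0("m", 1:7))
  parts <- stats::setNames(
    c("A", "A", "A", "A", "B", "B", "B", "B"), nodes)
  spanning <- stats::setNames(nodes == "D", nodes)
  hypergraph(nodes, he, parts = parts, spanning = spanning)
}
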