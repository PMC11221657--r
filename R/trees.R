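#' Parse and write newick trees
#'
#' Thin wrappers around `ape` that turn silent parse failures into errors.
#'
#' @param text newick string (single tree, terminated by `;`).
#' @return `parse_newick` returns an `ape::phylo`; `write_newick` a string.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick: ", substr(text, 1L, 60L))
  tr
}

#' @rdname parse_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

# tip-to-tip path lengths counting every edge as 1 (topological distances)
unit_cophenetic <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  stats::cophenetic(tree)
}

# four-point condition on any positive tree metric: the pairing with the
# strictly smallest distance sum is the induced quartet topology
classify_quartet <- function(s1, s2, s3, tol = 1e-9) {
  m <- pmin(s1, s2, s3)
  hit <- (s1 - m < tol) + (s2 - m < tol) + (s3 - m < tol)
  out <- integer(length(m))
  out[hit == 1L & s1 - m < tol] <- 1L
  out[hit == 1L & s2 - m < tol] <- 2L
  out[hit == 1L & s3 - m < tol] <- 3L
  out  # 0 = unresolved (tied minima, i.e. a star quartet)
}

#' Induced quartet topology of four tips
#'
#' Restricts the tree to four named tips (one per group, given in group order
#' G1..G4) and returns the induced unrooted pairing: `"12|34"` (G1 with G2),
#' `"13|24"`, `"14|23"`, or `"unresolved"` for a star quartet.
#'
#' @param tree an `ape::phylo`.
#' @param tips character vector of exactly four tip labels.
#' @return one of `"12|34"`, `"13|24"`, `"14|23"`, `"unresolved"`.
#' @export
quartet_topology <- function(tree, tips) {
  stopifnot(length(tips) == 4L)
  if (!all(tips %in% tree$tip.label))
    stop("missing tips: ", paste(setdiff(tips, tree$tip.label), collapse = ", "))
  sub <- ape::keep.tip(tree, tips)
  d <- unit_cophenetic(sub)
  s1 <- d[tips[1], tips[2]] + d[tips[3], tips[4]]
  s2 <- d[tips[1], tips[3]] + d[tips[2], tips[4]]
  s3 <- d[tips[1], tips[4]] + d[tips[2], tips[3]]
  c("unresolved", "12|34", "13|24", "14|23")[classify_quartet(s1, s2, s3) + 1L]
}

#' Topology weights of a window tree over four groups
#'
#' The weight of each of the three quartet resolutions is the fraction of
#' one-tip-per-group subtrees whose induced topology matches it, following
#' the iterative-subtree-sampling idea of topology weighting. When the number
#' of combinations is at most `max_exact` all are enumerated; otherwise
#' `n_samples` Monte Carlo draws are used. Unresolved (star) subtrees
#' contribute 1/3 to each weight, so weights always sum to 1.
#'
#' Weight order matches [quartet_topology()] pairings with the groups in the
#' supplied order: `w1` = (G1,G2)|(G3,G4), `w2` = (G1,G3)|(G2,G4),
#' `w3` = (G1,G4)|(G2,G3). Which discordant pairing plays the role of the
#' "introgression topology" is the caller's designation.
#'
#' @param tree an `ape::phylo` containing all group tips.
#' @param groups list of four non-overlapping character vectors of tip labels.
#' @param max_exact enumerate exactly up to this many combinations.
#' @param n_samples Monte Carlo sample count beyond `max_exact`.
#' @param seed optional seed for the Monte Carlo path.
#' @return named numeric `c(w1, w2, w3)` summing to 1, with attributes
#'   `n_combinations` and `exact`.
#' @export
topology_weights <- function(tree, groups, max_exact = 10000L,
                             n_samples = 10000L, seed = NULL) {
  stopifnot(length(groups) == 4L)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("every group must contain at least one tip")
  all_tips <- unlist(groups)
  if (anyDuplicated(all_tips)) stop("groups must be disjoint")
  if (!all(all_tips %in% tree$tip.label))
    stop("missing tips: ",
         paste(setdiff(all_tips, tree$tip.label), collapse = ", "))
  sub <- if (length(all_tips) < length(tree$tip.label))
    ape::keep.tip(tree, all_tips) else tree
  d <- unit_cophenetic(sub)
  idx <- lapply(groups, function(g) match(g, rownames(d)))
  sizes <- vapply(idx, length, 1L)
  n_comb <- prod(sizes)
  exact <- n_comb <= max_exact
  if (exact) {
    combos <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]], idx[[4]]))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    combos <- cbind(
      idx[[1]][sample.int(sizes[1], n_samples, TRUE)],
      idx[[2]][sample.int(sizes[2], n_samples, TRUE)],
      idx[[3]][sample.int(sizes[3], n_samples, TRUE)],
      idx[[4]][sample.int(sizes[4], n_samples, TRUE)])
  }
  s1 <- d[combos[, c(1, 2), drop = FALSE]] + d[combos[, c(3, 4), drop = FALSE]]
  s2 <- d[combos[, c(1, 3), drop = FALSE]] + d[combos[, c(2, 4), drop = FALSE]]
  s3 <- d[combos[, c(1, 4), drop = FALSE]] + d[combos[, c(2, 3), drop = FALSE]]
  cls <- classify_quartet(s1, s2, s3)
  n <- length(cls)
  w <- c(sum(cls == 1L), sum(cls == 2L), sum(cls == 3L)) / n
  w <- w + sum(cls == 0L) / (3 * n)
  names(w) <- c("w1", "w2", "w3")
  attr(w, "n_combinations") <- n_comb
  attr(w, "exact") <- exact
  w
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, optionally
#' normalized by the maximum 2(n-3) for the shared tip set.
#'
#' @param t1,t2 `ape::phylo` trees on identical tip sets.
#' @param normalized return the normalized distance in `[0, 1]`.
#' @return numeric RF distance.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical tip set")
  as.numeric(phangorn::RF.dist(t1, t2, normalize = normalized,
                               check.labels = TRUE))
}

#' Path length between two tips of a species tree
#'
#' Sum of branch lengths on the tip-to-tip path; with an ASTRAL-style species
#' tree this is the coalescent distance between the species.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param sp1,sp2 tip labels.
#' @return numeric distance (0 for `sp1 == sp2`).
#' @export
coalescent_distance <- function(tree, sp1, sp2) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must carry complete branch lengths")
  if (!all(c(sp1, sp2) %in% tree$tip.label))
    stop("missing tip(s): ", paste(setdiff(c(sp1, sp2), tree$tip.label),
                                   collapse = ", "))
  if (sp1 == sp2) return(0)
  d <- stats::cophenetic(tree)
  unname(d[sp1, sp2])
}
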