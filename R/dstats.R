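#' Frequency-weighted ABBA/BABA/BBAA site-pattern sums
#'
#' For a trio arrangement (((P1,P2),P3),O) with per-species alt-allele
#' frequencies p1, p2, p3, pO the sums are
#' `S_ABBA = sum (1-p1) p2 p3 (1-pO)`, `S_BABA = sum p1 (1-p2) p3 (1-pO)` and
#' `S_BBAA = sum p1 p2 (1-p3) (1-pO)`. Sites where any frequency is undefined
#' are skipped.
#'
#' @param freqs species x site frequency matrix (rownames = species), e.g.
#'   from [species_frequencies()] or [simulate_allele_frequencies()].
#' @param trio character vector of four species labels, ordered P1, P2, P3,
#'   outgroup.
#' @return object of class `site_pattern_sums`: list with `abba`, `baba`,
#'   `bbaa`, `n_sites`.
#' @export
site_pattern_sums <- function(freqs, trio) {
  stopifnot(length(trio) == 4L)
  if (!all(trio %in% rownames(freqs)))
    stop("missing species: ", paste(setdiff(trio, rownames(freqs)),
                                    collapse = ", "))
  p <- freqs[trio, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0L
  if (!any(ok)) stop("no usable sites for trio")
  p1 <- p[1L, ok]; p2 <- p[2L, ok]; p3 <- p[3L, ok]; po <- p[4L, ok]
  structure(list(abba = sum((1 - p1) * p2 * p3 * (1 - po)),
                 baba = sum(p1 * (1 - p2) * p3 * (1 - po)),
                 bbaa = sum(p1 * p2 * (1 - p3) * (1 - po)),
                 n_sites = sum(ok)),
            class = "site_pattern_sums")
}

#' D statistic from site-pattern sums
#'
#' `D = (S_ABBA - S_BABA) / (S_ABBA + S_BABA)`; positive values indicate
#' excess allele sharing between P2 and P3. Returns `NA` with a warning when
#' the denominator is zero.
#'
#' @param sums a [site_pattern_sums()] object.
#' @return numeric D in `[-1, 1]` (or `NA`).
#' @export
d_statistic <- function(sums) {
  den <- sums$abba + sums$baba
  if (den == 0) {
    warning("D undefined: S_ABBA + S_BABA is zero")
    return(NA_real_)
  }
  (sums$abba - sums$baba) / den
}

#' Dp statistic: site-pattern estimate of the introgressed proportion
#'
#' `Dp = (S_ABBA - S_BABA) / (S_ABBA + S_BBAA)`, reported in `[0, 1]`;
#' negative raw values are clamped to 0 and flagged via the `clamped`
#' attribute.
#'
#' @param sums a [site_pattern_sums()] object.
#' @return numeric Dp with attribute `clamped`.
#' @export
dp_statistic <- function(sums) {
  den <- sums$abba + sums$bbaa
  if (den == 0) {
    warning("Dp undefined: S_ABBA + S_BBAA is zero")
    return(NA_real_)
  }
  raw <- (sums$abba - sums$baba) / den
  out <- max(0, raw)
  attr(out, "clamped") <- raw < 0
  out
}

#' f4-ratio estimate of the admixture fraction
#'
#' Donor-substitution estimator: the numerator is the usual
#' `S_ABBA - S_BABA = sum (p2 - p1) p3 (1 - pO)` and the denominator replaces
#' P2 by the donor P3, `sum (p3 - p1) p3 (1 - pO)`, the expected numerator
#' under complete introgression. The ratio is clamped to `[0, 1]` with a
#' `clamped` attribute; use `clamp = FALSE` for the raw value.
#'
#' The denominator contains the square of the donor frequency, so sampling
#' noise in a finite donor panel inflates it and biases the ratio toward
#' zero. When per-site allele counts are available (the `n_alleles`
#' attribute attached by [species_frequencies()], or passed explicitly) the
#' donor's `p3^2` term is debiased by subtracting the unbiased sampling
#' variance `p3 (1 - p3) / (n3 - 1)`; this needs at least 2 donor alleles
#' per site. Frequency tables without counts (e.g. simulated true
#' frequencies) are used as is.
#'
#' @inheritParams site_pattern_sums
#' @param clamp clamp the estimate into `[0, 1]`.
#' @param n_alleles optional species x site matrix of allele counts used for
#'   the donor-squared bias correction (default: taken from
#'   `attr(freqs, "n_alleles")`).
#' @return numeric admixture-fraction estimate.
#' @export
f4_ratio <- function(freqs, trio, clamp = TRUE,
                     n_alleles = attr(freqs, "n_alleles")) {
  stopifnot(length(trio) == 4L)
  p <- freqs[trio, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0L
  if (!any(ok)) stop("no usable sites for trio")
  p1 <- p[1L, ok]; p2 <- p[2L, ok]; p3 <- p[3L, ok]; po <- p[4L, ok]
  p3_sq <- p3^2
  if (!is.null(n_alleles)) {
    n3 <- n_alleles[trio[3L], ok]
    corr <- ifelse(n3 >= 2L, p3 * (1 - p3) / (n3 - 1), 0)
    p3_sq <- p3_sq - corr
  }
  num <- sum((p2 - p1) * p3 * (1 - po))
  den <- sum((p3_sq - p1 * p3) * (1 - po))
  if (den == 0) {
    warning("f4-ratio undefined: zero denominator")
    return(NA_real_)
  }
  raw <- num / den
  if (!clamp) return(raw)
  out <- min(1, max(0, raw))
  attr(out, "clamped") <- raw < 0 || raw > 1
  out
}

#' Block-jackknife significance test for D
#'
#' Splits the usable sites (in genomic order) into `n_blocks` contiguous,
#' near-equal blocks and applies the delete-one block jackknife to D:
#' `SE^2 = (m-1)/m * sum (D_-i - mean(D_-i))^2`, `Z = D / SE`, two-sided
#' normal p-value. When all leave-one-out values coincide (SE = 0) the result
#' is flagged degenerate with `Z = +/-Inf` and `p = 0`.
#'
#' @inheritParams site_pattern_sums
#' @param n_blocks number of contiguous site blocks (default 20).
#' @return list with `D`, `se`, `Z`, `p`, `n_blocks`, `n_sites`, `degenerate`.
#' @export
jackknife_test <- function(freqs, trio, n_blocks = 20L) {
  p <- freqs[trio, , drop = FALSE]
  ok <- which(colSums(is.na(p)) == 0L)
  if (length(ok) < n_blocks)
    stop("fewer usable sites (", length(ok), ") than blocks (", n_blocks, ")")
  p1 <- p[1L, ok]; p2 <- p[2L, ok]; p3 <- p[3L, ok]; po <- p[4L, ok]
  abba <- (1 - p1) * p2 * p3 * (1 - po)
  baba <- p1 * (1 - p2) * p3 * (1 - po)
  block <- ceiling(seq_along(ok) / (length(ok) / n_blocks))
  block[block > n_blocks] <- n_blocks
  ab <- rowsum(abba, block)
  bb <- rowsum(baba, block)
  A <- sum(ab); B <- sum(bb)
  if (A + B == 0) stop("D undefined on every block")
  D <- (A - B) / (A + B)
  d_loo <- (A - ab - (B - bb)) / (A - ab + (B - bb))
  m <- n_blocks
  se <- sqrt((m - 1) / m * sum((d_loo - mean(d_loo))^2))
  degenerate <- se == 0
  z <- if (degenerate) sign(D) * Inf else D / se
  list(D = D, se = se, Z = z, p = 2 * pnorm(-abs(z)),
       n_blocks = m, n_sites = length(ok), degenerate = degenerate)
}

# tips descending from `node` in a phylo
node_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, node_tips, tree = tree))
}

#' f-branch matrix: branch-resolved gene-flow signal
#'
#' For every branch b of a rooted species tree (internal and terminal,
#' excluding branches on the outgroup side) and every candidate donor tip C
#' outside clade(b) and its sister clade:
#' `fb(C) = min over B in clade(b) of median over A in sister(b) of
#' f4_ratio(A, B, C, outgroup)`, with negative values floored at 0. Cells
#' where C falls inside clade(b) or the sister clade are undefined (`NA`).
#'
#' @param species_tree rooted `ape::phylo` whose tips (apart from `outgroup`)
#'   all have rows in `freqs`.
#' @param freqs species x site frequency matrix.
#' @param outgroup outgroup tip label.
#' @return object of class `fbranch`: matrix with one row per branch (labelled
#'   by its clade's sorted tip set), one column per non-outgroup tip, with
#'   attributes `branch_tips` (list) and `terminal` (logical).
#' @export
f_branch <- function(species_tree, freqs, outgroup) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (!outgroup %in% species_tree$tip.label)
    stop("outgroup not in the species tree")
  tips <- setdiff(species_tree$tip.label, outgroup)
  if (!all(c(tips, outgroup) %in% rownames(freqs)))
    stop("frequency table must cover every species-tree tip")
  ntip <- length(species_tree$tip.label)
  rows <- list(); labels <- character(0); terminal <- logical(0)
  for (e in seq_len(nrow(species_tree$edge))) {
    child <- species_tree$edge[e, 2L]
    parent <- species_tree$edge[e, 1L]
    clade <- node_tips(species_tree, child)
    if (outgroup %in% clade) next
    sisters <- setdiff(node_tips(species_tree, parent), c(clade, outgroup))
    if (length(sisters) == 0L) next
    donors <- setdiff(tips, c(clade, sisters))
    fb <- setNames(rep(NA_real_, length(tips)), tips)
    for (C in donors) {
      per_b <- vapply(clade, function(B) {
        med <- median(vapply(sisters, function(A)
          f4_ratio(freqs, c(A, B, C, outgroup), clamp = FALSE), numeric(1)))
        med
      }, numeric(1))
      fb[C] <- max(0, min(per_b))
    }
    rows[[length(rows) + 1L]] <- fb
    labels <- c(labels, paste(sort(clade), collapse = ","))
    terminal <- c(terminal, length(clade) == 1L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- labels
  attr(out, "terminal") <- terminal
  attr(out, "outgroup") <- outgroup
  class(out) <- c("fbranch", class(out))
  out
}

#' @export
print.fbranch <- function(x, digits = 3, ...) {
  cat("f-branch matrix:", nrow(x), "branches x", ncol(x), "donor tips",
      "(outgroup:", attr(x, "outgroup"), ")\n")
  m <- unclass(x)
  attr(m, "terminal") <- NULL
  attr(m, "outgroup") <- NULL
  print(round(m, digits), ...)
  invisible(x)
}

#' Discordant-topology count test (DCT)
#'
#' Under incomplete lineage sorting alone the two discordant quartet
#' topologies are equally frequent; introgression inflates one. A 1-df
#' chi-squared test of `n_disc1` vs `n_disc2` against the equal-frequency
#' null.
#'
#' @param n_disc1,n_disc2 window counts of the two discordant topologies.
#' @return list with `statistic`, `p`, `n_disc1`, `n_disc2`.
#' @export
dct_test <- function(n_disc1, n_disc2) {
  if (n_disc1 + n_disc2 < 1L) stop("both discordant counts are zero")
  e <- (n_disc1 + n_disc2) / 2
  stat <- (n_disc1 - e)^2 / e + (n_disc2 - e)^2 / e
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       n_disc1 = n_disc1, n_disc2 = n_disc2)
}

#' Branch-length test (BLT) on window trees
#'
#' Classifies each window tree by its quartet pairing over the four groups
#' (ordered P1, P2, P3, O) and compares, by one-sided rank sum, the P2-P3
#' tip distances in (P2,P3)-sister windows against the P1-P3 distances in
#' (P1,P3)-sister windows. P3 -> P2 introgression makes the former
#' stochastically smaller (`alternative = "less"`, the default). Windows are
#' classified with [topology_weights()] argmax when groups hold several tips.
#'
#' @param window_trees list of `ape::phylo` with branch lengths.
#' @param groups list of four tip-label vectors, ordered P1, P2, P3, O.
#' @param min_windows minimum windows per discordant class (default 5).
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `statistic`, `p`, `n_p2p3`, `n_p1p3`, `skipped`.
#' @export
blt_test <- function(window_trees, groups, min_windows = 5L,
                     alternative = "less") {
  stopifnot(length(groups) == 4L)
  single <- all(vapply(groups, length, 1L) == 1L)
  cls <- vapply(window_trees, function(tr) {
    if (single) {
      quartet_topology(tr, unlist(groups))
    } else {
      w <- topology_weights(tr, groups)
      if (max(w) - sort(w, decreasing = TRUE)[2L] < 1e-12) "unresolved"
      else c("12|34", "13|24", "14|23")[which.max(w)]
    }
  }, character(1))
  pair_dist <- function(tr, g1, g2) {
    d <- stats::cophenetic(tr)
    mean(d[g1, g2, drop = FALSE])
  }
  d_p2p3 <- vapply(window_trees[cls == "14|23"], pair_dist,
                   numeric(1), g1 = groups[[2]], g2 = groups[[3]])
  d_p1p3 <- vapply(window_trees[cls == "13|24"], pair_dist,
                   numeric(1), g1 = groups[[1]], g2 = groups[[3]])
  if (length(d_p2p3) < min_windows || length(d_p1p3) < min_windows)
    return(list(statistic = NA_real_, p = NA_real_,
                n_p2p3 = length(d_p2p3), n_p1p3 = length(d_p1p3),
                skipped = TRUE))
  wt <- wilcox.test(d_p2p3, d_p1p3, alternative = alternative, exact = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_p2p3 = length(d_p2p3), n_p1p3 = length(d_p1p3), skipped = FALSE)
}
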