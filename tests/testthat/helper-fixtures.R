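# shared fixtures and independent oracles

# small genotype matrix with evenly spaced sites on one chromosome
make_geno <- function(g, chrom = "chr1", spacing = 1000L, pos = NULL) {
  g <- as.matrix(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("s", seq_len(nrow(g)))
  if (is.null(pos)) pos <- seq_len(ncol(g)) * spacing
  geno_matrix(g, data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                            stringsAsFactors = FALSE))
}

simple_map <- function(geno, species) {
  data.frame(sample = rownames(geno$geno), species = species,
             is_reference = TRUE, basins = "", stringsAsFactors = FALSE)
}

# independent quartet oracle: exhaustive search over the tree's bipartitions
oracle_quartet <- function(tree, tips) {
  un <- ape::unroot(tree)
  parts <- ape::prop.part(un)
  labs <- attr(parts, "labels")
  pairings <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  for (k in seq_along(pairings)) {
    pr <- pairings[[k]]
    qr <- setdiff(1:4, pr)
    for (p in parts) {
      side <- labs[p]
      other <- setdiff(labs, side)
      if ((all(tips[pr] %in% side) && all(tips[qr] %in% other)) ||
          (all(tips[qr] %in% side) && all(tips[pr] %in% other)))
        return(c("12|34", "13|24", "14|23")[k])
    }
  }
  "unresolved"
}

# brute-force topology weights: iterate every one-tip-per-group combination
# through the bipartition oracle
oracle_weights <- function(tree, groups) {
  combos <- expand.grid(groups, stringsAsFactors = FALSE)
  w <- c(0, 0, 0)
  for (i in seq_len(nrow(combos))) {
    cls <- oracle_quartet(tree, as.character(unlist(combos[i, ])))
    if (cls == "unresolved") w <- w + 1 / 3
    else w[match(cls, c("12|34", "13|24", "14|23"))] <-
        w[match(cls, c("12|34", "13|24", "14|23"))] + 1
  }
  w / nrow(combos)
}

# random tree with 4 groups of `k` tips each (labels a1.., b1.., c1.., d1..)
random_group_tree <- function(k, seed) {
  set.seed(seed)
  labs <- as.vector(outer(letters[1:4], seq_len(k), paste0))
  ape::rtree(4L * k, tip.label = sample(labs))
}

group_list <- function(k) {
  lapply(letters[1:4], function(l) paste0(l, seq_len(k)))
}

# drift step used by null simulations in tests (kept separate from the
# package's generator on purpose)
drift_beta <- function(p, f) rbeta(length(p), p * (1 - f) / f,
                                   (1 - p) * (1 - f) / f)

# four-population frequency table with no gene flow: P1 and P2 exchangeable
null_quartet_freqs <- function(n_sites) {
  p0 <- runif(n_sites, 0.05, 0.95)
  pabc <- drift_beta(p0, 0.1)
  pab <- drift_beta(pabc, 0.1)
  rbind(P1 = drift_beta(pab, 0.08), P2 = drift_beta(pab, 0.08),
        P3 = drift_beta(pabc, 0.15), O = drift_beta(p0, 0.3))
}

# randomized probability integral transform of a discrete observed statistic
# against its simulated null; exactly Uniform(0,1) when obs ~ null
randomized_pit <- function(obs, null) {
  (sum(null > obs) + runif(1) * sum(null == obs)) / length(null)
}

# uniform random interval set on one chromosome
random_regions <- function(n, len, chrom_len) {
  s <- floor(runif(n) * (chrom_len - len + 1))
  data.frame(chrom = "chr1", start = s, end = s + len)
}
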