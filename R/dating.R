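#' Site-index windows of a fixed SNP count
#'
#' Splits the sites of a genotype matrix into consecutive blocks of
#' `snps_per_window` sites (the last, shorter block is kept only when at
#' least half-full).
#'
#' @param x a [geno_matrix()].
#' @param snps_per_window sites per window (default 200).
#' @return list of integer site-index vectors.
#' @export
snp_windows <- function(x, snps_per_window = 200L) {
  n <- ncol(x$geno)
  starts <- seq(1L, n, by = snps_per_window)
  w <- lapply(starts, function(s) s:min(s + snps_per_window - 1L, n))
  if (length(w) > 1L && length(w[[length(w)]]) < snps_per_window / 2)
    w <- w[-length(w)]
  w
}

#' Nucleotide diversity (pi) of a taxon over a site window
#'
#' Per-site unbiased heterozygosity `2 p (1-p) n/(n-1)` (n = non-missing
#' allele count), averaged over the window's accessible sites (those with at
#' least 2 non-missing alleles).
#'
#' @param x a [geno_matrix()].
#' @param map sample map.
#' @param taxon species label.
#' @param sites integer site indices (default: all sites).
#' @param reference_only restrict to reference individuals (default FALSE).
#' @return numeric pi per site.
#' @export
nucleotide_diversity <- function(x, map, taxon, sites = NULL,
                                 reference_only = FALSE) {
  ids <- map$sample[map$species == taxon &
                    (!reference_only | map$is_reference)]
  if (length(ids) < 2L) stop("taxon ", taxon, " needs >= 2 individuals")
  g <- x$geno[ids, , drop = FALSE]
  if (!is.null(sites)) g <- g[, sites, drop = FALSE]
  n <- 2 * colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / n
  ok <- n >= 2
  if (!any(ok)) stop("no accessible sites in window")
  h <- 2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)
  mean(h)
}

#' Average pairwise divergence (Dxy) between two taxa over a site window
#'
#' Per-site `pA (1-pB) + pB (1-pA)`, averaged over sites accessible in both
#' taxa.
#'
#' @inheritParams nucleotide_diversity
#' @param taxonA,taxonB species labels.
#' @return numeric Dxy per site.
#' @export
dxy <- function(x, map, taxonA, taxonB, sites = NULL,
                reference_only = FALSE) {
  freq_of <- function(taxon) {
    ids <- map$sample[map$species == taxon &
                      (!reference_only | map$is_reference)]
    if (length(ids) == 0L) stop("no samples for taxon ", taxon)
    f <- allele_frequencies(x, ids)
    if (!is.null(sites)) f[sites] else f
  }
  pa <- freq_of(taxonA)
  pb <- freq_of(taxonB)
  ok <- !is.na(pa) & !is.na(pb)
  if (!any(ok)) stop("no accessible sites in window")
  mean(pa[ok] * (1 - pb[ok]) + pb[ok] * (1 - pa[ok]))
}

#' Assign each window to the candidate sister taxon of a focal taxon
#'
#' A window is assigned to candidate X only when, in its gene tree, every
#' focal tip's closest candidate clade (smallest topological tip distance to
#' any of the candidate's tips) is X; windows with split or tied affinities
#' are `"mixed"`. Windows whose trees lack required tips are `NA` (skipped,
#' with a count in the `n_skipped` attribute).
#'
#' @param window_trees list of `ape::phylo`.
#' @param focal_tips tip labels of the focal taxon.
#' @param candidate_tips named list, candidate label -> tip labels.
#' @return character vector of assignments (candidate label, `"mixed"`, or
#'   `NA`), with attribute `n_skipped`.
#' @export
assign_window_sister <- function(window_trees, focal_tips, candidate_tips) {
  need <- c(focal_tips, unlist(candidate_tips))
  out <- vapply(window_trees, function(tr) {
    if (!all(need %in% tr$tip.label)) return(NA_character_)
    d <- unit_cophenetic(tr)
    per_tip <- vapply(focal_tips, function(ft) {
      dm <- vapply(candidate_tips, function(ct) min(d[ft, ct]), numeric(1))
      if (sum(dm == min(dm)) > 1L) return(NA_character_)
      names(candidate_tips)[which.min(dm)]
    }, character(1))
    if (anyNA(per_tip) || length(unique(per_tip)) > 1L) "mixed"
    else per_tip[[1L]]
  }, character(1))
  attr(out, "n_skipped") <- sum(is.na(out))
  out
}

#' Net-divergence estimate of the introgression time
#'
#' `T_generations = max(0, (mean(Dxy) - mean(pi)) / (2 mu))`, converted to
#' years by the generation time. `pi` should be the donor taxon's diversity
#' in the same windows, a proxy for the diversity of the ancestral
#' population at the time of the gene-flow event.
#'
#' @param dxy_windows per-window Dxy values (focal vs donor).
#' @param pi_windows matching per-window donor pi values.
#' @param mu mutation rate per site per generation (> 0).
#' @param generation_time generation time in years.
#' @return object of class `date_estimate`: list with `t_years`,
#'   `t_generations`, `mu`, `generation_time`, `n_windows`, `floored`.
#' @export
introgression_time <- function(dxy_windows, pi_windows, mu, generation_time) {
  stopifnot(length(dxy_windows) == length(pi_windows),
            length(dxy_windows) >= 1L)
  if (mu <= 0) stop("mu must be positive")
  raw <- (mean(dxy_windows) - mean(pi_windows)) / (2 * mu)
  tg <- max(0, raw)
  structure(list(t_years = tg * generation_time, t_generations = tg,
                 mu = mu, generation_time = generation_time,
                 n_windows = length(dxy_windows), floored = raw < 0),
            class = "date_estimate")
}

#' @export
print.date_estimate <- function(x, ...) {
  cat(sprintf("introgression time: %.0f years (%.0f generations; %d windows)\n",
              x$t_years, x$t_generations, x$n_windows))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap CI: %.0f - %.0f years\n",
                x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Bootstrap confidence interval for the introgression time
#'
#' Resamples windows (jointly for Dxy and pi) with replacement and reports
#' the 2.5/97.5 percentile interval of the recomputed time in years.
#'
#' @inheritParams introgression_time
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return numeric `c(low, high)` in years.
#' @export
bootstrap_ci <- function(dxy_windows, pi_windows, mu, generation_time,
                         n_boot = 1000L, seed = 1L) {
  n <- length(dxy_windows)
  if (n < 2L) stop("need >= 2 windows for a bootstrap CI")
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  dx <- matrix(dxy_windows[idx], nrow = n_boot)
  pi <- matrix(pi_windows[idx], nrow = n_boot)
  t_boot <- pmax(0, (rowMeans(dx) - rowMeans(pi)) / (2 * mu)) *
    generation_time
  unname(quantile(t_boot, c(0.025, 0.975)))
}

#' Date an introgression event from assigned windows
#'
#' Convenience wrapper: computes per-window Dxy (focal vs donor) and donor
#' pi over the supplied windows, the point estimate, and its bootstrap CI.
#'
#' @param x a [geno_matrix()].
#' @param map sample map.
#' @param focal,donor species labels.
#' @param windows list of site-index vectors (e.g. from [snp_windows()]).
#' @param mu mutation rate per site per generation.
#' @param generation_time generation time in years.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return a `date_estimate` with an added `ci` element.
#' @export
date_introgression <- function(x, map, focal, donor, windows, mu,
                               generation_time, n_boot = 1000L, seed = 1L) {
  dx <- vapply(windows, function(w)
    dxy(x, map, focal, donor, sites = w), numeric(1))
  pw <- vapply(windows, function(w)
    nucleotide_diversity(x, map, donor, sites = w), numeric(1))
  est <- introgression_time(dx, pw, mu, generation_time)
  est$ci <- if (length(windows) >= 2L)
    bootstrap_ci(dx, pw, mu, generation_time, n_boot = n_boot, seed = seed)
  else c(NA_real_, NA_real_)
  est$dxy_windows <- dx
  est$pi_windows <- pw
  est
}
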