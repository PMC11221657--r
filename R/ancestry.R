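#' Build a reference panel of per-group allele frequencies
#'
#' Frequencies are computed from reference-panel individuals only and clamped
#' into `[eps, 1 - eps]` so that fixed differences keep finite likelihoods.
#' Sites where any group has no non-missing reference call are dropped from
#' the panel.
#'
#' @param x a [geno_matrix()].
#' @param map sample map.
#' @param groups character vector of species labels (each its own ancestry
#'   component); default: all reference species in `map`.
#' @param eps clamping constant (default 1e-4).
#' @return object of class `reference_panel`: list with `freq` (K x J
#'   matrix), `sites` (site table of retained sites), `site_index` (columns
#'   of `x` retained), `groups`.
#' @export
build_reference_panel <- function(x, map, groups = NULL, eps = 1e-4) {
  stopifnot(inherits(x, "geno_matrix"))
  if (is.null(groups))
    groups <- sort(unique(map$species[map$is_reference]))
  if (length(groups) < 2L) stop("need at least two reference groups")
  f <- matrix(NA_real_, nrow = length(groups), ncol = ncol(x$geno),
              dimnames = list(groups, NULL))
  for (g in groups) {
    ids <- map$sample[map$species == g & map$is_reference]
    if (length(ids) < 2L)
      stop("reference group ", g, " has fewer than 2 individuals")
    f[g, ] <- allele_frequencies(x, ids)
  }
  keep <- which(colSums(is.na(f)) == 0L)
  f <- pmin(pmax(f[, keep, drop = FALSE], eps), 1 - eps)
  structure(list(freq = f, sites = x$sites[keep, , drop = FALSE],
                 site_index = keep, groups = groups),
            class = "reference_panel")
}

# EM for one individual's ancestry proportions with fixed panel frequencies.
# g: alt dosages at the panel sites (NA allowed); F: K x J panel frequencies.
ancestry_em <- function(g, F, tol = 1e-6, max_iter = 2000L, trace = FALSE,
                        q_init = NULL) {
  ok <- !is.na(g)
  if (!any(ok)) stop("no non-missing sites for this individual")
  g <- g[ok]
  F <- F[, ok, drop = FALSE]
  K <- nrow(F)
  J <- ncol(F)
  q <- if (is.null(q_init)) rep(1 / K, K) else unname(q_init)
  ll <- function(p) sum(g * log(p) + (2 - g) * log1p(-p))
  trace_ll <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- as.vector(q %*% F)                     # length J
    A <- (q * F) * rep(g / p, each = K)         # K x J expected alt alleles
    B <- (q * (1 - F)) * rep((2 - g) / (1 - p), each = K)
    q_new <- (rowSums(A) + rowSums(B)) / (2 * J)
    if (trace) trace_ll <- c(trace_ll, ll(p))
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  p <- as.vector(q %*% F)
  list(q = setNames(q, rownames(F)), loglik = ll(p), iterations = it,
       converged = converged, n_sites = J,
       loglik_trace = if (trace) trace_ll else NULL)
}

#' Supervised ancestry proportions for one individual
#'
#' Maximizes the binomial genotype likelihood
#' `prod_j Bin(g_j; 2, sum_k q_k f_kj)` over the ancestry simplex by EM,
#' holding the reference-panel frequencies fixed (supervised admixture).
#' Convergence is declared when the largest change in any component is below
#' `tol`; otherwise the best iterate is returned with `converged = FALSE`.
#'
#' @param x a [geno_matrix()], or a bare dosage vector over the panel sites.
#' @param sample sample id (when `x` is a `geno_matrix`).
#' @param panel a [build_reference_panel()].
#' @param tol convergence tolerance on max |delta q|.
#' @param max_iter iteration cap.
#' @param trace record the per-iteration log-likelihood.
#' @return list with `q` (named, sums to 1), `loglik`, `iterations`,
#'   `converged`, `n_sites`, `loglik_trace`.
#' @export
supervised_ancestry <- function(x, sample = NULL, panel, tol = 1e-6,
                                max_iter = 2000L, trace = FALSE) {
  g <- if (inherits(x, "geno_matrix")) {
    stopifnot(!is.null(sample))
    x$geno[sample, panel$site_index]
  } else x
  if (length(g) != ncol(panel$freq))
    stop("dosage vector length must match the panel")
  ancestry_em(g, panel$freq, tol = tol, max_iter = max_iter, trace = trace)
}

#' Moving-block bootstrap standard errors for ancestry proportions
#'
#' Resamples contiguous blocks of `block_sites` panel sites (moving blocks,
#' with replacement) to rebuild pseudo-genomes, re-estimates q on each, and
#' reports the per-component standard deviation across replicates.
#'
#' @inheritParams supervised_ancestry
#' @param n_boot bootstrap replicates (default 100).
#' @param block_sites sites per block (default 200).
#' @param seed integer seed.
#' @return named numeric vector of standard errors.
#' @export
bootstrap_se <- function(x, sample = NULL, panel, n_boot = 100L,
                         block_sites = 200L, seed = 1L, tol = 1e-4,
                         max_iter = 2000L) {
  g <- if (inherits(x, "geno_matrix")) {
    stopifnot(!is.null(sample))
    x$geno[sample, panel$site_index]
  } else x
  J <- length(g)
  if (J < 2L * block_sites) block_sites <- max(1L, J %/% 4L)
  n_blocks <- ceiling(J / block_sites)
  starts_all <- seq_len(max(1L, J - block_sites + 1L))
  # warm-start every replicate from the full-data estimate
  q_full <- ancestry_em(g, panel$freq, tol = tol, max_iter = max_iter)$q
  set.seed(as.integer(seed))
  qs <- vapply(seq_len(n_boot), function(b) {
    st <- sample(starts_all, n_blocks, replace = TRUE)
    idx <- as.vector(outer(0:(block_sites - 1L), st, `+`))[seq_len(J)]
    ancestry_em(g[idx], panel$freq[, idx, drop = FALSE], tol = tol,
                max_iter = max_iter, q_init = q_full)$q
  }, numeric(nrow(panel$freq)))
  apply(qs, 1L, sd)
}

#' Call hybrid status from ancestry proportions and standard errors
#'
#' A component contributes when the lower end of its standard-error interval,
#' `q_k - se_k`, is at least `threshold` (default 0.1); an individual is a
#' hybrid when at least two components contribute. The default threshold is
#' chosen to capture hybrids up to second-generation backcrosses.
#'
#' @param q named ancestry proportions.
#' @param se matching standard errors.
#' @param threshold lower-bound cutoff (default 0.1).
#' @return list with `hybrid` (logical) and `components` (names).
#' @export
call_hybrid <- function(q, se, threshold = 0.1) {
  stopifnot(length(q) == length(se))
  contributing <- (q - se) >= threshold - 1e-12
  list(hybrid = sum(contributing) >= 2L,
       components = names(q)[contributing])
}

# joint EM update of Q and F for unsupervised admixture; missing genotypes
# drop out of both numerator and denominator.
admixture_em_once <- function(G, K, q0, f0, tol, max_iter) {
  n <- nrow(G); J <- ncol(G)
  M <- !is.na(G)
  Gz <- G; Gz[!M] <- 0L
  W <- 2L * M
  Q <- q0; F <- f0
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- Q %*% F                       # n x J
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    Ra <- Gz / P                       # n x J
    Rb <- (W - Gz) / (1 - P)
    A_q <- (Ra %*% t(F)) * Q           # n x K: sum_j a_ikj
    B_q <- (Rb %*% t(1 - F)) * Q
    Q_new <- (A_q + B_q) / rowSums(W)
    A_f <- t(Q) %*% Ra * F             # K x J: sum_i a_ikj
    B_f <- t(Q) %*% Rb * (1 - F)
    F_new <- A_f / (A_f + B_f)
    F_new[is.na(F_new)] <- 0.5
    F_new <- pmin(pmax(F_new, 1e-6), 1 - 1e-6)
    ll <- sum((Gz * log(P) + (W - Gz) * log1p(-P))[M])
    if (it > 1L && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-8)) {
      converged <- TRUE
      Q <- Q_new; F <- F_new
      break
    }
    ll_prev <- ll
    Q <- Q_new; F <- F_new
  }
  P <- pmin(pmax(Q %*% F, 1e-12), 1 - 1e-12)
  ll <- sum((Gz * log(P) + (W - Gz) * log1p(-P))[M])
  list(Q = Q, F = F, loglik = ll, iterations = it, converged = converged)
}

#' Unsupervised admixture by EM with seeded restarts
#'
#' Joint maximum-likelihood estimation of per-individual ancestry proportions
#' Q and per-component allele frequencies F under the standard admixture
#' binomial model, by EM from `n_restarts` random starts; the restart with
#' the best likelihood is kept. When `ref_freqs` is given (component x site),
#' components are relabelled greedily by correlation with those reference
#' frequencies to resolve label switching.
#'
#' @param x a [geno_matrix()] (rows = individuals to analyse).
#' @param K number of ancestry components (>= 2).
#' @param n_restarts random restarts (default 5).
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param ref_freqs optional reference frequency matrix for label matching.
#' @return list with `Q` (rows named by sample), `F`, `loglik`, `converged`.
#' @export
unsupervised_admixture <- function(x, K, n_restarts = 5L, seed = 1L,
                                   tol = 1e-8, max_iter = 500L,
                                   ref_freqs = NULL) {
  stopifnot(inherits(x, "geno_matrix"), K >= 2L)
  G <- x$geno
  if (nrow(G) < K) stop("need at least K individuals")
  set.seed(as.integer(seed))
  base_f <- colMeans(G, na.rm = TRUE) / 2
  best <- NULL
  for (r in seq_len(n_restarts)) {
    q0 <- matrix(rgamma(nrow(G) * K, 1), nrow(G), K)
    q0 <- q0 / rowSums(q0)
    f0 <- pmin(pmax(matrix(rep(base_f, each = K), K, ncol(G)) +
                    matrix(runif(K * ncol(G), -0.1, 0.1), K), 0.01), 0.99)
    fit <- admixture_em_once(G, K, q0, f0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!is.null(ref_freqs)) {
    stopifnot(ncol(ref_freqs) == ncol(G))
    perm <- integer(K)
    avail <- seq_len(K)
    for (k in seq_len(min(K, nrow(ref_freqs)))) {
      cors <- vapply(avail, function(j)
        suppressWarnings(cor(ref_freqs[k, ], best$F[j, ])), numeric(1))
      pick <- avail[which.max(cors)]
      perm[k] <- pick
      avail <- setdiff(avail, pick)
    }
    perm[perm == 0L] <- avail
    best$Q <- best$Q[, perm, drop = FALSE]
    best$F <- best$F[perm, , drop = FALSE]
    rownames(best$F) <- rownames(ref_freqs)[seq_len(K)]
    colnames(best$Q) <- rownames(best$F)
  }
  rownames(best$Q) <- rownames(G)
  best
}

#' Species-diagnostic SNP panel
#'
#' Retains sites where the focal species' reference individuals are fixed
#' (frequency exactly 0 or 1 among non-missing calls) for an allele whose
#' frequency is below `max_other_freq` in the reference individuals of every
#' other species. The diagnostic allele (ref or alt) is recorded per site.
#'
#' @param x a [geno_matrix()].
#' @param map sample map.
#' @param focal focal species label.
#' @param max_other_freq cross-species frequency ceiling (default 0.1).
#' @param others species to screen against (default: all other reference
#'   species).
#' @return object of class `diagnostic_panel`: data.frame with `chrom`,
#'   `pos`, `allele` ("ref"/"alt"), `site_index`; attribute `focal`.
#' @export
find_diagnostic_snps <- function(x, map, focal, max_other_freq = 0.1,
                                 others = NULL) {
  ids <- map$sample[map$species == focal & map$is_reference]
  if (length(ids) < 2L) stop("focal species needs >= 2 reference individuals")
  if (is.null(others))
    others <- setdiff(unique(map$species[map$is_reference]), focal)
  f_focal <- allele_frequencies(x, ids)
  f_oth <- do.call(rbind, lapply(others, function(s)
    allele_frequencies(x, map$sample[map$species == s & map$is_reference])))
  fixed_alt <- !is.na(f_focal) & f_focal == 1
  fixed_ref <- !is.na(f_focal) & f_focal == 0
  oth_ok <- colSums(is.na(f_oth)) == 0L
  alt_rare <- oth_ok & colSums(f_oth >= max_other_freq) == 0L
  ref_rare <- oth_ok & colSums((1 - f_oth) >= max_other_freq) == 0L
  keep_alt <- which(fixed_alt & alt_rare)
  keep_ref <- which(fixed_ref & ref_rare)
  idx <- sort(c(keep_alt, keep_ref))
  if (length(idx) == 0L)
    warning("no diagnostic SNPs found for ", focal)
  out <- data.frame(chrom = x$sites$chrom[idx], pos = x$sites$pos[idx],
                    allele = ifelse(idx %in% keep_alt, "alt", "ref"),
                    site_index = idx, stringsAsFactors = FALSE)
  attr(out, "focal") <- focal
  class(out) <- c("diagnostic_panel", class(out))
  out
}

#' Diagnostic-SNP genotype profile of an individual
#'
#' Over the non-missing panel sites: the proportions of sites homozygous for
#' the focal species' diagnostic allele, heterozygous, and homozygous for the
#' other allele. An F1 hybrid is near-fully heterozygous on both parents'
#' panels; a backcross shifts toward homozygous-diagnostic on the recurrent
#' parent's panel.
#'
#' @param x a [geno_matrix()].
#' @param sample sample id.
#' @param panel a [find_diagnostic_snps()] panel (or list of panels).
#' @return named numeric `c(hom_diagnostic, het, hom_other)` with attribute
#'   `n_sites`; for a list of panels, a data.frame with one row per panel.
#' @export
diagnostic_profile <- function(x, sample, panel) {
  if (is.list(panel) && !inherits(panel, "diagnostic_panel")) {
    rows <- lapply(panel, function(p) {
      pr <- diagnostic_profile(x, sample, p)
      data.frame(focal = attr(p, "focal"), sample = sample,
                 hom_diagnostic = pr[["hom_diagnostic"]], het = pr[["het"]],
                 hom_other = pr[["hom_other"]],
                 n_sites = attr(pr, "n_sites"), stringsAsFactors = FALSE)
    })
    return(do.call(rbind, c(rows, make.row.names = FALSE)))
  }
  g <- x$geno[sample, panel$site_index]
  ok <- !is.na(g)
  if (!any(ok)) stop("all panel sites missing for ", sample)
  g <- g[ok]
  diag_alt <- panel$allele[ok] == "alt"
  dose_diag <- ifelse(diag_alt, g, 2L - g)
  out <- c(hom_diagnostic = mean(dose_diag == 2L),
           het = mean(dose_diag == 1L),
           hom_other = mean(dose_diag == 0L))
  attr(out, "n_sites") <- sum(ok)
  out
}
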