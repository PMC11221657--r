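#' Top gene-flow counterpart of each species
#'
#' From an f-branch matrix, takes for each tip species the tip species with
#' the highest f-branch value against that species' terminal branch. Internal
#' branches are excluded so that only species pairs are compared. Ties are
#' broken by lexicographic species label with a warning; species whose
#' terminal-branch row is entirely undefined are dropped with a warning.
#'
#' @param fb an [f_branch()] matrix.
#' @return data.frame (class `counterpart_table`) with columns `species`,
#'   `counterpart`, `fb`, `tie`.
#' @export
top_counterparts <- function(fb) {
  stopifnot(inherits(fb, "fbranch"))
  terminal <- attr(fb, "terminal")
  if (sum(terminal) < 2L) stop("need at least two terminal branches")
  m <- unclass(fb)[terminal, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(m))) {
    sp <- rownames(m)[i]
    v <- m[i, ]
    v <- v[names(v) != sp]
    if (all(is.na(v))) {
      warning("no defined f-branch donors for species ", sp, "; dropped")
      next
    }
    mx <- max(v, na.rm = TRUE)
    best <- sort(names(v)[!is.na(v) & v == mx])
    if (length(best) > 1L)
      warning("tie for top counterpart of ", sp,
              "; keeping lexicographically first")
    out[[sp]] <- data.frame(species = sp, counterpart = best[1L], fb = mx,
                            tie = length(best) > 1L,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("every terminal row is undefined")
  tab <- do.call(rbind, c(out, make.row.names = FALSE))
  class(tab) <- c("counterpart_table", class(tab))
  tab
}

#' Keep one species of each mutual counterpart pair
#'
#' When two species are each other's top counterpart, the pair reflects a
#' single putative gene-flow event; one of the two (chosen by seeded
#' randomness) is retained to avoid pseudo-replication in the permutation
#' tests.
#'
#' @param table a [top_counterparts()] table.
#' @param seed integer seed.
#' @return the reduced table.
#' @export
dedupe_mutual_pairs <- function(table, seed = 1L) {
  set.seed(as.integer(seed))
  drop <- character(0)
  seen <- character(0)
  for (i in seq_len(nrow(table))) {
    x <- table$species[i]
    y <- table$counterpart[i]
    if (x %in% seen || y %in% seen) next
    j <- which(table$species == y)
    if (length(j) == 1L && table$counterpart[j] == x) {
      drop <- c(drop, sample(c(x, y), 1L))
      seen <- c(seen, x, y)
    }
  }
  table[!table$species %in% drop, , drop = FALSE]
}

# n_sim x n matrix of uniformly random counterpart indices (excluding self)
random_counterpart_draws <- function(n, n_sim) {
  r <- matrix(sample.int(n - 1L, n * n_sim, replace = TRUE),
              nrow = n_sim, ncol = n)
  r + (r >= rep(seq_len(n), each = n_sim))
}

#' Permutation test for drainage-basin sharing of top counterparts
#'
#' Observed statistic: the number of species whose top counterpart shares at
#' least one drainage basin with them. Null: each species draws a uniformly
#' random counterpart from the other tested species; the count of
#' basin-sharing draws is recorded for each of `n_sim` simulations, and the
#' p-value is the raw proportion of simulations with at least the observed
#' count.
#'
#' @param table a (deduplicated) counterpart table.
#' @param basins named list, species -> character vector of basin labels.
#' @param n_sim number of simulations (default 100000).
#' @param seed integer seed.
#' @param return_null also return the simulated counts.
#' @return list with `observed`, `p`, `sim_range`, `n_sim` (and `null` if
#'   requested).
#' @export
basin_permutation_test <- function(table, basins, n_sim = 100000L, seed = 1L,
                                   return_null = FALSE) {
  sp <- table$species
  n <- length(sp)
  if (n < 2L) stop("need at least two species")
  if (!all(sp %in% names(basins)) || !all(table$counterpart %in% names(basins)))
    stop("basin map must cover every tested species and counterpart")
  shares <- function(x, y) length(intersect(basins[[x]], basins[[y]])) > 0L
  observed <- sum(mapply(shares, sp, table$counterpart))
  share_mat <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    shares(sp[i], sp[j])))
  set.seed(as.integer(seed))
  draws <- random_counterpart_draws(n, n_sim)
  hit <- matrix(share_mat[cbind(rep(seq_len(n), each = n_sim),
                                as.vector(draws))],
                nrow = n_sim)
  counts <- rowSums(hit)
  out <- list(observed = observed, p = mean(counts >= observed),
              sim_range = range(counts), n_sim = n_sim)
  if (return_null) out$null <- counts
  out
}

#' Phylogenetic-distance z-scores of top counterparts
#'
#' For each species, the z-score of the coalescent distance to its top
#' counterpart relative to the mean and standard deviation of its distances
#' to all other tested species. `z <= -2` marks a significantly closer
#' counterpart, `z >= 2` a significantly more distant one. Undefined (zero
#' spread, or fewer than 3 comparison species) z-scores are `NA`.
#'
#' @param species_tree `ape::phylo` with branch lengths (coalescent units).
#' @param table a counterpart table.
#' @return the table with added `distance` and `z` columns.
#' @export
distance_zscores <- function(species_tree, table) {
  sp <- table$species
  need <- union(sp, table$counterpart)
  if (!all(need %in% species_tree$tip.label))
    stop("species tree missing tips: ",
         paste(setdiff(need, species_tree$tip.label), collapse = ", "))
  if (is.null(species_tree$edge.length))
    stop("species tree must carry branch lengths")
  d <- stats::cophenetic(species_tree)
  table$distance <- d[cbind(sp, table$counterpart)]
  table$z <- vapply(seq_along(sp), function(i) {
    others <- setdiff(sp, sp[i])
    if (length(others) < 3L) return(NA_real_)
    di <- d[sp[i], others]
    s <- sd(di)
    if (s == 0) return(NA_real_)
    (table$distance[i] - mean(di)) / s
  }, numeric(1))
  table
}

#' Permutation test for phylogenetic closeness of top counterparts
#'
#' Observed statistic: the number of species whose counterpart z-score (see
#' [distance_zscores()]) is at or beyond the threshold: `z <= -2` for
#' `direction = "closer"`, `z >= 2` for `direction = "farther"`. The null
#' draws uniformly random counterparts exactly as in
#' [basin_permutation_test()].
#'
#' @param table a counterpart table (z-scores are recomputed internally).
#' @param species_tree `ape::phylo` with branch lengths.
#' @param n_sim number of simulations.
#' @param seed integer seed.
#' @param direction `"closer"` or `"farther"`.
#' @param return_null also return the simulated counts.
#' @return list with `observed`, `p`, `sim_range`, `n_sim` (and `null`).
#' @export
distance_permutation_test <- function(table, species_tree, n_sim = 100000L,
                                      seed = 1L,
                                      direction = c("closer", "farther"),
                                      return_null = FALSE) {
  direction <- match.arg(direction)
  tab <- distance_zscores(species_tree, table)
  sp <- tab$species
  n <- length(sp)
  d <- stats::cophenetic(species_tree)
  # z of every possible counterpart, per species
  zmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(sp, sp[i])
    if (length(others) < 3L) next
    mu <- mean(d[sp[i], others]); s <- sd(d[sp[i], others])
    if (s == 0) next
    zmat[i, ] <- (d[sp[i], sp] - mu) / s
  }
  extreme <- if (direction == "closer") zmat <= -2 else zmat >= 2
  extreme[is.na(extreme)] <- FALSE
  obs_z <- tab$z
  observed <- if (direction == "closer")
    sum(obs_z <= -2, na.rm = TRUE) else sum(obs_z >= 2, na.rm = TRUE)
  set.seed(as.integer(seed))
  draws <- random_counterpart_draws(n, n_sim)
  hit <- matrix(extreme[cbind(rep(seq_len(n), each = n_sim),
                              as.vector(draws))],
                nrow = n_sim)
  counts <- rowSums(hit)
  out <- list(observed = observed, p = mean(counts >= observed),
              sim_range = range(counts), n_sim = n_sim)
  if (return_null) out$null <- counts
  out
}

#' Repeat a counterpart permutation test over mutual-pair resolutions
#'
#' The mutual-pair deduplication is random; the protocol re-draws it
#' `n_repeats` times, reruns the test on each reduced table, and reports the
#' highest p-value (conservative over the dedup choice).
#'
#' @param table a full (pre-dedup) counterpart table.
#' @param test_fun function(table, seed) -> list with a `p` element.
#' @param n_repeats number of repeats (default 10).
#' @param seed integer master seed (dedup and test sub-seeds derive from it).
#' @return list with `p_max`, `p_values`, `seeds`.
#' @export
repeat_max_p <- function(table, test_fun, n_repeats = 10L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L * n_repeats)
  ps <- vapply(seq_len(n_repeats), function(r) {
    tab <- dedupe_mutual_pairs(table, seed = seeds[r])
    test_fun(tab, seeds[n_repeats + r])$p
  }, numeric(1))
  list(p_max = max(ps), p_values = ps, seeds = seeds[seq_len(n_repeats)])
}
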