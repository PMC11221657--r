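#' Configuration for the synthetic multi-species SNP simulator
#'
#' Bundles everything the generator needs: a rooted species tree whose branch
#' lengths are drift amounts F (Balding-Nichols, each in (0,1)), per-species
#' sample sizes, a site budget spread over chromosomes, planted introgression
#' tracts, hybrid pedigrees, a species-to-drainage-basin map, and one seed
#' from which all randomness flows.
#'
#' @param species_tree rooted tree (`ape::phylo` or newick string); branch
#'   lengths are Balding-Nichols drift parameters F, each strictly in (0,1).
#' @param n_per_species integer, individuals simulated per species; either a
#'   single value or a named vector over tip labels.
#' @param n_sites total number of biallelic sites.
#' @param chromosome_lengths named numeric vector, chromosome -> length in bp.
#' @param introgression_events list of events, each a list with elements
#'   `donor`, `recipient`, `chrom`, `start`, `end` (bp, closed interval on
#'   site positions) and `alpha` (admixture fraction in `[0,1]`).
#' @param hybrid_specs list of specs, each a list with elements `a`, `b`
#'   (parent species), `pedigree` (one of "F1", "BC1_A", "BC1_B") and `count`.
#' @param basin_map named list, species -> character vector of basin labels.
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(species_tree, n_per_species = 10L, n_sites = 10000L,
                       chromosome_lengths = c(chr1 = 1e6),
                       introgression_events = list(),
                       hybrid_specs = list(),
                       basin_map = list(), seed = 1L) {
  if (is.character(species_tree))
    species_tree <- parse_newick(species_tree)
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree))
    stop("species_tree must be rooted")
  if (is.null(species_tree$edge.length))
    stop("species_tree must carry branch lengths (drift F per branch)")
  if (any(species_tree$edge.length <= 0 | species_tree$edge.length >= 1))
    stop("all drift parameters F must lie strictly in (0, 1)")
  if (n_sites < 1) stop("n_sites must be positive")
  sp <- species_tree$tip.label
  if (length(n_per_species) == 1L && is.null(names(n_per_species)))
    n_per_species <- setNames(rep(as.integer(n_per_species), length(sp)), sp)
  if (!all(sp %in% names(n_per_species)))
    stop("n_per_species must cover every species in the tree")
  if (any(n_per_species < 1)) stop("n_per_species must be >= 1")
  if (is.null(names(chromosome_lengths)))
    stop("chromosome_lengths must be named")
  for (ev in introgression_events) {
    stopifnot(all(c("donor", "recipient", "chrom", "start", "end", "alpha")
                  %in% names(ev)))
    if (!ev$donor %in% sp || !ev$recipient %in% sp)
      stop("introgression event names unknown species: ",
           ev$donor, " -> ", ev$recipient)
    if (!ev$chrom %in% names(chromosome_lengths))
      stop("introgression event on unknown chromosome ", ev$chrom)
    if (ev$alpha < 0 || ev$alpha > 1) stop("alpha must lie in [0, 1]")
    if (ev$start < 1 || ev$end > chromosome_lengths[[ev$chrom]] ||
        ev$start > ev$end)
      stop("event interval outside chromosome ", ev$chrom)
  }
  for (hs in hybrid_specs) {
    stopifnot(all(c("a", "b", "pedigree", "count") %in% names(hs)))
    if (!hs$a %in% sp || !hs$b %in% sp)
      stop("hybrid spec names unknown species")
    if (!hs$pedigree %in% c("F1", "BC1_A", "BC1_B"))
      stop("unknown pedigree label: ", hs$pedigree)
  }
  structure(list(species_tree = species_tree,
                 n_per_species = n_per_species[sp],
                 n_sites = as.integer(n_sites),
                 chromosome_lengths = chromosome_lengths,
                 introgression_events = introgression_events,
                 hybrid_specs = hybrid_specs,
                 basin_map = basin_map,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One Balding-Nichols drift step: child frequencies given parent frequencies p
# and drift F. Beta with mean p and variance p(1-p)F; F -> 0 is the no-drift
# limit and is returned exactly.
bn_drift <- function(p, f) {
  if (f < 1e-12) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), a, b)
}

#' Simulate drift-structured per-species allele frequencies
#'
#' Ancestral (root) frequencies are drawn Uniform(0.05, 0.95) to keep sites
#' informative, then drift down the species tree: each branch applies a
#' Balding-Nichols step, a Beta draw with mean equal to the parent frequency
#' and variance p(1-p)F for the branch's drift parameter F. Site coordinates
#' are scattered uniformly over the configured chromosomes.
#'
#' @param config a [sim_config()].
#' @return an object of class `freq_table`: list with `freq` (species x site
#'   matrix of alt-allele frequencies) and `sites` (data.frame with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 8L)
  set.seed(seeds[1L])
  tr <- ape::reorder.phylo(config$species_tree, "cladewise")
  n <- config$n_sites
  cl <- config$chromosome_lengths
  n_chr <- pmax(1L, round(n * cl / sum(cl)))
  # keep the total site budget exact
  while (sum(n_chr) != n) {
    i <- if (sum(n_chr) > n) which.max(n_chr) else which.min(n_chr)
    n_chr[i] <- n_chr[i] + sign(n - sum(n_chr))
  }
  sites <- do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(chrom = names(cl)[i],
               pos = sort(sample.int(cl[[i]], n_chr[i])),
               stringsAsFactors = FALSE)
  }))
  sites$ref <- "A"
  sites$alt <- "T"
  rownames(sites) <- NULL

  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  freq <- matrix(NA_real_, nrow = nnode, ncol = n)
  root <- ntip + 1L
  freq[root, ] <- runif(n, 0.05, 0.95)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    chd <- tr$edge[e, 2L]
    freq[chd, ] <- bn_drift(freq[par, ], tr$edge.length[e])
  }
  out <- freq[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  structure(list(freq = out, sites = sites), class = "freq_table")
}

#' Blend donor allele frequencies into a recipient tract
#'
#' Inside the event's tract the recipient species' frequency becomes
#' `(1 - alpha) * recipient + alpha * donor`; everything else is untouched.
#' This is the deterministic frequency-level imprint of an admixture pulse of
#' proportion alpha.
#'
#' @param freqs a `freq_table` from [simulate_allele_frequencies()].
#' @param event a single introgression event (see [sim_config()]).
#' @return the modified `freq_table`.
#' @export
apply_introgression <- function(freqs, event) {
  stopifnot(inherits(freqs, "freq_table"))
  if (!event$donor %in% rownames(freqs$freq) ||
      !event$recipient %in% rownames(freqs$freq))
    stop("unknown species in introgression event")
  idx <- which(freqs$sites$chrom == event$chrom &
               freqs$sites$pos >= event$start & freqs$sites$pos <= event$end)
  if (length(idx) == 0L)
    stop("introgression tract contains no sites: ",
         event$chrom, ":", event$start, "-", event$end)
  a <- event$alpha
  freqs$freq[event$recipient, idx] <-
    (1 - a) * freqs$freq[event$recipient, idx] +
    a * freqs$freq[event$donor, idx]
  freqs
}

#' Draw diploid genotypes from per-species allele frequencies
#'
#' Each individual's genotype at each site is Binomial(2, p) for its species'
#' frequency p. All simulated individuals are flagged as reference-panel
#' members; hybrids added later by [make_hybrids()] are not.
#'
#' @param freqs a `freq_table`.
#' @param n_per_species named integer vector over species.
#' @param seed integer seed.
#' @param basin_map optional named list species -> basin labels, recorded in
#'   the sample map.
#' @return list with `geno` (a [geno_matrix()]) and `map` (sample map
#'   data.frame: `sample`, `species`, `is_reference`, `basins`).
#' @export
sample_genotypes <- function(freqs, n_per_species, seed = 1L,
                             basin_map = list()) {
  stopifnot(inherits(freqs, "freq_table"))
  if (any(freqs$freq < 0 | freqs$freq > 1))
    stop("allele frequencies must lie in [0, 1]")
  set.seed(as.integer(seed))
  sp <- rownames(freqs$freq)
  if (length(n_per_species) == 1L && is.null(names(n_per_species)))
    n_per_species <- setNames(rep(as.integer(n_per_species), length(sp)), sp)
  n_sites <- ncol(freqs$freq)
  rows <- list()
  ids <- character(0)
  species_of <- character(0)
  for (s in sp) {
    k <- n_per_species[[s]]
    p <- freqs$freq[s, ]
    g <- matrix(rbinom(k * n_sites, 2L, rep(p, each = k)), nrow = k)
    rows[[s]] <- g
    ids <- c(ids, sprintf("%s_%02d", s, seq_len(k)))
    species_of <- c(species_of, rep(s, k))
  }
  geno <- do.call(rbind, rows)
  rownames(geno) <- ids
  basins <- vapply(species_of, function(s)
    paste(basin_map[[s]], collapse = ";"), character(1))
  map <- data.frame(sample = ids, species = species_of,
                    is_reference = TRUE, basins = unname(basins),
                    stringsAsFactors = FALSE)
  list(geno = geno_matrix(geno, freqs$sites), map = map)
}

# draw one gamete per site from a random individual of `pool` (rows of geno)
random_gamete <- function(geno, pool) {
  n_sites <- ncol(geno)
  donor <- pool[sample.int(length(pool), n_sites, replace = TRUE)]
  g <- geno[cbind(donor, seq_len(n_sites))]
  rbinom(n_sites, 1L, g / 2)
}

#' Add F1 and first-generation backcross hybrids to a genotype matrix
#'
#' F1 individuals receive, at every site, one allele drawn from a random
#' individual of each parent species. BC1_A crosses an internally constructed
#' F1 back to species A (BC1_B to species B). Sites are treated as unlinked.
#' Hybrids are flagged `is_reference = FALSE` in the sample map.
#'
#' @param geno a [geno_matrix()] of pure individuals.
#' @param map matching sample map.
#' @param hybrid_specs list of specs (see [sim_config()]).
#' @param seed integer seed.
#' @return list with augmented `geno`, `map`, and `truth` (data.frame:
#'   `sample`, `pedigree`, `parent_a`, `parent_b`).
#' @export
make_hybrids <- function(geno, map, hybrid_specs, seed = 1L) {
  stopifnot(inherits(geno, "geno_matrix"))
  set.seed(as.integer(seed))
  g <- geno$geno
  new_rows <- list()
  truth <- list()
  counter <- 0L
  for (hs in hybrid_specs) {
    if (!hs$pedigree %in% c("F1", "BC1_A", "BC1_B"))
      stop("unknown pedigree label: ", hs$pedigree)
    pool_a <- which(map$species == hs$a & map$is_reference)
    pool_b <- which(map$species == hs$b & map$is_reference)
    if (length(pool_a) == 0L || length(pool_b) == 0L)
      stop("both parent species need at least one non-hybrid individual")
    for (i in seq_len(hs$count)) {
      counter <- counter + 1L
      f1 <- random_gamete(g, pool_a) + random_gamete(g, pool_b)
      hg <- switch(hs$pedigree,
        F1 = f1,
        BC1_A = rbinom(ncol(g), 1L, f1 / 2) + random_gamete(g, pool_a),
        BC1_B = rbinom(ncol(g), 1L, f1 / 2) + random_gamete(g, pool_b))
      id <- sprintf("hyb_%s_%s_%s_%02d", hs$pedigree, hs$a, hs$b, counter)
      new_rows[[id]] <- hg
      truth[[id]] <- data.frame(sample = id, pedigree = hs$pedigree,
                                parent_a = hs$a, parent_b = hs$b,
                                stringsAsFactors = FALSE)
    }
  }
  if (length(new_rows)) {
    hmat <- do.call(rbind, new_rows)
    rownames(hmat) <- names(new_rows)
    g <- rbind(g, hmat)
    map <- rbind(map, data.frame(sample = names(new_rows),
                                 species = "hybrid",
                                 is_reference = FALSE, basins = "",
                                 stringsAsFactors = FALSE))
  }
  list(geno = geno_matrix(g, geno$sites), map = map,
       truth = if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
               else data.frame(sample = character(0), pedigree = character(0),
                               parent_a = character(0), parent_b = character(0)))
}

#' Simulate window gene trees from a controlled topology mixture
#'
#' Each window's species-level quartet topology is drawn from a mixture over
#' the three resolutions of the four groups (in group order G1..G4): class 1
#' pairs (G1,G2)|(G3,G4) (the species-tree topology), class 2 pairs
#' (G1,G3)|(G2,G4), class 3 pairs (G1,G4)|(G2,G3). Each species is then
#' expanded into a clade of its individuals (tips `species_i`), with unit
#' branch lengths.
#'
#' @param species character vector of exactly four species (group order).
#' @param n_per_species individuals per species (single value or named).
#' @param windows data.frame with `chrom`, `start`, `end` (half-open bp).
#' @param mixture either a length-3 probability vector used for all windows or
#'   an `nrow(windows)` x 3 matrix of per-window mixtures; rows must sum to 1
#'   (tolerance 1e-9).
#' @param seed integer seed.
#' @return list of `ape::phylo` trees, one per window, with attributes
#'   `windows` (the input data.frame) and `true_class` (integer vector).
#' @export
simulate_window_trees <- function(species, n_per_species, windows, mixture,
                                  seed = 1L) {
  stopifnot(length(species) == 4L)
  set.seed(as.integer(seed))
  nw <- nrow(windows)
  if (is.null(dim(mixture)))
    mixture <- matrix(mixture, nrow = nw, ncol = 3L, byrow = TRUE)
  if (nrow(mixture) != nw || ncol(mixture) != 3L)
    stop("mixture must be length 3 or an n_windows x 3 matrix")
  if (any(abs(rowSums(mixture) - 1) > 1e-9))
    stop("mixture weights must sum to 1 per window")
  if (length(n_per_species) == 1L && is.null(names(n_per_species)))
    n_per_species <- setNames(rep(as.integer(n_per_species), 4L), species)
  clade <- vapply(species, function(s) {
    k <- n_per_species[[s]]
    tips <- paste0(s, "_", seq_len(k), ":1")
    if (k == 1L) tips else paste0("(", paste(tips, collapse = ","), "):1")
  }, character(1))
  pair_of <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  newick_for <- function(cls) {
    p <- pair_of[[cls]]
    q <- setdiff(1:4, p)
    paste0("((", clade[p[1]], ",", clade[p[2]], "):1,(",
           clade[q[1]], ",", clade[q[2]], "):1);")
  }
  cls <- apply(mixture, 1L, function(w) sample.int(3L, 1L, prob = w))
  trees <- lapply(cls, function(k) parse_newick(newick_for(k)))
  attr(trees, "windows") <- windows
  attr(trees, "true_class") <- cls
  trees
}

#' Run the full synthetic-data generator
#'
#' Drift-structured frequencies, planted introgression tracts, genotype
#' sampling, and hybrid construction, driven entirely by the config's seed.
#'
#' @param config a [sim_config()].
#' @return list with `freqs` (post-introgression `freq_table`), `geno`, `map`,
#'   and `truth` (list: `hybrids` data.frame, `regions` per-event data.frame,
#'   `alpha` per-event numeric).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L)
  freqs <- simulate_allele_frequencies(config)
  regions <- list()
  for (ev in config$introgression_events) {
    freqs <- apply_introgression(freqs, ev)
    regions[[length(regions) + 1L]] <-
      data.frame(recipient = ev$recipient, donor = ev$donor,
                 chrom = ev$chrom, start = ev$start, end = ev$end,
                 alpha = ev$alpha, stringsAsFactors = FALSE)
  }
  gs <- sample_genotypes(freqs, config$n_per_species, seed = seeds[2L],
                         basin_map = config$basin_map)
  hy <- make_hybrids(gs$geno, gs$map, config$hybrid_specs, seed = seeds[3L])
  truth <- list(hybrids = hy$truth,
                regions = if (length(regions)) do.call(rbind, regions)
                          else data.frame(),
                alpha = vapply(config$introgression_events,
                               function(e) e$alpha, numeric(1)))
  list(freqs = freqs, geno = hy$geno, map = hy$map, truth = truth)
}

#' Simulate a diverged taxon pair with known split time
#'
#' Mutation-drift toy model for dating calibration: per site, either a shared
#' ancestral polymorphism (probability `prop_poly`, frequency Uniform(0.05,
#' 0.95) in both taxa), a lineage-specific fixed difference (probability
#' `mu * t_gen` in each taxon independently), or an invariant site. The
#' expected net divergence `Dxy - pi` is therefore `2 * mu * t_gen`,
#' matching the estimator in [introgression_time()].
#'
#' @param n_windows,sites_per_window genome size in 200-SNP-style windows.
#' @param n_per_taxon diploid individuals per taxon.
#' @param mu mutation rate per site per generation.
#' @param t_gen split time in generations.
#' @param prop_poly per-site probability of shared ancestral polymorphism.
#' @param seed integer seed.
#' @return list with `geno` ([geno_matrix()], taxa "focal" and "donor"),
#'   `map`, `windows` (site-index list), `t_gen`.
#' @export
simulate_divergence_pair <- function(n_windows = 40L, sites_per_window = 250L,
                                     n_per_taxon = 10L, mu = 1e-6,
                                     t_gen = 5000, prop_poly = 0.01,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  n_sites <- n_windows * sites_per_window
  cat_p <- c(poly = prop_poly, fixed_f = mu * t_gen, fixed_d = mu * t_gen)
  if (sum(cat_p) >= 1) stop("mu * t_gen and prop_poly too large")
  u <- runif(n_sites)
  p_f <- numeric(n_sites)
  p_d <- numeric(n_sites)
  poly <- u < cat_p[1L]
  p_shared <- runif(sum(poly), 0.05, 0.95)
  p_f[poly] <- p_shared
  p_d[poly] <- p_shared
  fix_f <- u >= cat_p[1L] & u < cat_p[1L] + cat_p[2L]
  fix_d <- u >= cat_p[1L] + cat_p[2L] & u < sum(cat_p)
  p_f[fix_f] <- 1
  p_d[fix_d] <- 1
  freq <- rbind(focal = p_f, donor = p_d)
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  ft <- structure(list(freq = freq, sites = sites), class = "freq_table")
  gs <- sample_genotypes(ft, c(focal = n_per_taxon, donor = n_per_taxon),
                         seed = derive_seeds(seed, 2L)[2L])
  windows <- split(seq_len(n_sites),
                   rep(seq_len(n_windows), each = sites_per_window))
  list(geno = gs$geno, map = gs$map, windows = unname(windows), t_gen = t_gen)
}

#' Write / read the generator's truth set as JSON
#'
#' @param truth truth list from [simulate_dataset()] (optionally with a
#'   `window_mixture` element).
#' @param path file path.
#' @return `read_truth` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(out$hybrids)) out$hybrids <- as.data.frame(out$hybrids)
  if (!is.null(out$regions)) out$regions <- as.data.frame(out$regions)
  out
}
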