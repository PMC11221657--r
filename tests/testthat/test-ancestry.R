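# two well-separated species with planted hybrids, reused across tests
ancestry_fixture <- function(n_sites = 4000L, n_per = 10L, seed = 17L,
                             f1 = 2L, bc1 = 2L) {
  cfg <- sim_config("(P:0.45,Q:0.45);", n_per_species = n_per,
                    n_sites = n_sites,
                    chromosome_lengths = c(chr1 = 1e6),
                    hybrid_specs = list(
                      list(a = "P", b = "Q", pedigree = "F1", count = f1),
                      list(a = "P", b = "Q", pedigree = "BC1_A",
                           count = bc1)),
                    seed = seed)
  simulate_dataset(cfg)
}

test_that("reference panels count alleles and clamp fixed frequencies", {
  g <- rbind(a1 = c(2L, 0L), a2 = c(2L, 1L), b1 = c(0L, 0L), b2 = c(0L, NA))
  gm <- make_geno(g)
  map <- simple_map(gm, c("A", "A", "B", "B"))
  panel <- build_reference_panel(gm, map)
  expect_equal(unname(panel$freq["A", ]), c(1 - 1e-4, 0.25))
  expect_equal(unname(panel$freq["B", 2]), 1e-4)  # missing call excluded
  expect_error(build_reference_panel(gm, map[-1, ]), "fewer than 2")
})

test_that("supervised EM recovers forced ancestry configurations", {
  J <- 500L
  panel <- structure(list(
    freq = rbind(A = rep(1 - 1e-4, J), B = rep(1e-4, J)),
    sites = data.frame(chrom = "chr1", pos = seq_len(J), ref = "A",
                       alt = "T"),
    site_index = seq_len(J), groups = c("A", "B")),
    class = "reference_panel")
  pure <- supervised_ancestry(rep(2L, J), panel = panel)
  expect_gt(pure$q[["A"]], 0.99)
  het <- supervised_ancestry(rep(1L, J), panel = panel)
  expect_equal(unname(het$q), c(0.5, 0.5), tolerance = 1e-6)
  # likelihood is non-decreasing across every EM iteration
  set.seed(23)
  g <- rbinom(J, 2L, 0.7)
  fit <- supervised_ancestry(g, panel = panel, trace = TRUE)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("supervised estimates are invariant to site order and duplication", {
  sim <- ancestry_fixture(n_sites = 1500L)
  panel <- build_reference_panel(sim$geno, sim$map)
  id <- sim$truth$hybrids$sample[1L]
  g <- sim$geno$geno[id, panel$site_index]
  fit <- supervised_ancestry(g, panel = panel)
  set.seed(9)
  perm <- sample(length(g))
  panel_perm <- panel
  panel_perm$freq <- panel$freq[, perm]
  fit_perm <- supervised_ancestry(g[perm], panel = panel_perm)
  expect_equal(fit$q, fit_perm$q, tolerance = 1e-8)
  panel_dup <- panel
  panel_dup$freq <- cbind(panel$freq, panel$freq)
  fit_dup <- supervised_ancestry(c(g, g), panel = panel_dup)
  expect_equal(fit$q, fit_dup$q, tolerance = 1e-6)
})

test_that("pedigree ancestry is recovered within tolerance", {
  sim <- ancestry_fixture(n_sites = 10000L, seed = 29L)
  panel <- build_reference_panel(sim$geno, sim$map)
  truth <- sim$truth$hybrids
  for (i in seq_len(nrow(truth))) {
    fit <- supervised_ancestry(sim$geno, truth$sample[i], panel)
    expected <- if (truth$pedigree[i] == "F1") 0.5 else 0.75
    expect_lt(abs(fit$q[["P"]] - expected), 0.05)
  }
})

test_that("block-bootstrap SEs shrink with data and are seed-stable", {
  sim <- ancestry_fixture(n_sites = 8000L, seed = 31L, f1 = 1L, bc1 = 0L)
  panel <- build_reference_panel(sim$geno, sim$map)
  id_pure <- sim$map$sample[sim$map$species == "P"][1L]
  se_pure <- bootstrap_se(sim$geno, id_pure, panel, n_boot = 40L, seed = 3L)
  expect_true(all(se_pure < 0.01))  # no variability at q ~ (1, 0)
  id_f1 <- sim$truth$hybrids$sample[1L]
  g <- sim$geno$geno[id_f1, panel$site_index]
  half <- seq_len(length(g) %/% 2)
  panel_half <- panel
  panel_half$freq <- panel$freq[, half]
  se_half <- bootstrap_se(g[half], panel = panel_half, n_boot = 60L,
                          block_sites = 100L, seed = 5L)
  se_full <- bootstrap_se(g, panel = panel, n_boot = 60L,
                          block_sites = 100L, seed = 5L)
  ratio <- mean(se_half / se_full)
  expect_gt(ratio, 1)          # doubling sites reduces the SE ...
  expect_lt(abs(ratio - sqrt(2)), 0.6)  # ... roughly like sqrt(2)
  expect_identical(bootstrap_se(g, panel = panel, n_boot = 20L, seed = 11L),
                   bootstrap_se(g, panel = panel, n_boot = 20L, seed = 11L))
})

test_that("hybrid-call rule uses the lower end of the SE interval", {
  res <- call_hybrid(c(A = 0.55, B = 0.45), c(0.05, 0.05))
  expect_true(res$hybrid)
  expect_equal(sort(res$components), c("A", "B"))
  expect_false(call_hybrid(c(0.95, 0.05), c(0.02, 0.02))$hybrid)
  expect_false(call_hybrid(c(0.88, 0.12), c(0.03, 0.03))$hybrid)  # 0.09 < 0.1
  expect_true(call_hybrid(c(0.88, 0.12), c(0.03, 0.02))$hybrid)   # 0.10 >= 0.1
})

test_that("unsupervised admixture separates species and finds hybrid origin", {
  sim <- ancestry_fixture(n_sites = 2000L, n_per = 8L, seed = 37L, f1 = 0L,
                          bc1 = 0L)
  fit <- unsupervised_admixture(sim$geno, K = 2L, seed = 4L)
  q_p <- fit$Q[sim$map$species == "P", 1L]
  # one-hot rows up to label switching
  comp <- if (mean(q_p) > 0.5) 1L else 2L
  expect_true(all(abs(fit$Q[sim$map$species == "P", comp] - 1) < 0.02))
  expect_true(all(abs(fit$Q[sim$map$species == "Q", comp]) < 0.02))
  fit2 <- unsupervised_admixture(sim$geno, K = 2L, seed = 4L)
  expect_identical(fit$Q, fit2$Q)  # deterministic under the seed

  # hybrid-origin population: a 50/50 blend of P and Q frequencies that has
  # drifted since its origin -> every individual ~50/50 at K = 2, its own
  # component at K = 3
  cfg <- sim_config("((P:0.45,Q:0.45):0.01,R:0.02);", n_per_species = 8L,
                    n_sites = 3000L, seed = 41L)
  fr <- simulate_allele_frequencies(cfg)
  set.seed(42)
  blend <- 0.5 * fr$freq["P", ] + 0.5 * fr$freq["Q", ]
  fr$freq["R", ] <- drift_beta(pmin(pmax(blend, 0.01), 0.99), 0.1)
  gs <- sample_genotypes(fr, c(P = 8L, Q = 8L, R = 8L), seed = 43L)
  panelPQ <- build_reference_panel(gs$geno, gs$map, groups = c("P", "Q"))
  k2 <- unsupervised_admixture(gs$geno, K = 2L, seed = 6L,
                               ref_freqs = panelPQ$freq)
  qr <- k2$Q[gs$map$species == "R", 1L]
  expect_true(all(abs(qr - 0.5) < 0.1))
  k3 <- unsupervised_admixture(gs$geno, K = 3L, seed = 6L)
  # at K = 3 the hybrid-origin population is dominated by one component
  r_mean <- colMeans(k3$Q[gs$map$species == "R", ])
  own <- which.max(r_mean)
  expect_gt(r_mean[own], 0.8)
  expect_lt(max(colMeans(k3$Q[gs$map$species == "P", ])[own],
                colMeans(k3$Q[gs$map$species == "Q", ])[own]), 0.35)
})

test_that("diagnostic panels apply the fixation and rarity rules", {
  # columns: 1 focal fixed alt & absent elsewhere (diag alt)
  #          2 focal fixed alt, other species at 0.2 (excluded)
  #          3 focal at 0.75 (not fixed, excluded)
  #          4 focal fixed ref & alt common elsewhere (diag ref)
  g <- rbind(f1 = c(2L, 2L, 2L, 0L), f2 = c(2L, 2L, 1L, 0L),
             o1 = c(0L, 0L, 0L, 2L), o2 = c(0L, 1L, 0L, 2L),
             p1 = c(0L, 0L, 0L, 2L), p2 = c(0L, 0L, 0L, 2L))
  gm <- make_geno(g)
  map <- simple_map(gm, c("F", "F", "X", "X", "Y", "Y"))
  panel <- find_diagnostic_snps(gm, map, "F")
  expect_equal(panel$site_index, c(1L, 4L))
  expect_equal(panel$allele, c("alt", "ref"))
  expect_warning(find_diagnostic_snps(gm, map, "X"), "no diagnostic")
})

test_that("diagnostic profiles expose F1 and backcross structure", {
  sim <- ancestry_fixture(n_sites = 6000L, seed = 47L)
  panels <- lapply(c("P", "Q"), function(s)
    find_diagnostic_snps(sim$geno, sim$map, s))
  truth <- sim$truth$hybrids
  f1_id <- truth$sample[truth$pedigree == "F1"][1L]
  prof <- diagnostic_profile(sim$geno, f1_id, panels)
  expect_true(all(prof$het > 0.9))  # heterozygous on both parents' panels
  bc_id <- truth$sample[truth$pedigree == "BC1_A"][1L]
  prof_bc <- diagnostic_profile(sim$geno, bc_id, panels)
  n <- prof_bc$n_sites
  band <- 3 * sqrt(0.25 / n)
  expect_lt(abs(prof_bc$hom_diagnostic[prof_bc$focal == "P"] - 0.5),
            band[1L])
  expect_lt(abs(prof_bc$het[prof_bc$focal == "Q"] - 0.5), band[2L])
  pure_id <- sim$map$sample[sim$map$species == "P"][1L]
  prof_pure <- diagnostic_profile(sim$geno, pure_id, panels[[1L]])
  expect_gt(prof_pure[["hom_diagnostic"]], 0.97)
})
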