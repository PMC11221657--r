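test_that("Balding-Nichols drift has the right limits and moments", {
  # no-drift limit: child equals parent
  cfg <- sim_config("(A:1e-13,B:1e-13);", n_sites = 200L, seed = 5L)
  fr <- simulate_allele_frequencies(cfg)
  expect_equal(fr$freq["A", ], fr$freq["B", ], tolerance = 1e-9)

  # mean of child frequencies equals parent; parent p = 0.5 is not directly
  # configurable, so drift two tips from the same ancestor with F = 0.5 and
  # check E[child] = ancestral mean 0.5 within 3 SE
  cfg2 <- sim_config("(A:0.5,B:0.5);", n_sites = 1e5L, seed = 11L)
  fr2 <- simulate_allele_frequencies(cfg2)
  # Var(child) = E[p(1-p)] F + Var(p); p ~ U(0.05, 0.95)
  vr <- 0.1825 * 0.5 + 0.0675
  se <- sqrt(vr / 1e5)
  expect_lt(abs(mean(fr2$freq["A", ]) - 0.5), 3 * se)
  expect_true(all(fr2$freq >= 0 & fr2$freq <= 1))
})

test_that("frequency simulation is deterministic under the seed", {
  cfg <- sim_config("((A:0.1,B:0.2):0.1,C:0.3);", n_sites = 500L, seed = 42L)
  expect_identical(simulate_allele_frequencies(cfg),
                   simulate_allele_frequencies(cfg))
  trees1 <- simulate_window_trees(c("A", "B", "C", "D"), 2L,
                                  data.frame(chrom = "chr1", start = 0,
                                             end = 1e4),
                                  c(0.5, 0.3, 0.2), seed = 9L)
  trees2 <- simulate_window_trees(c("A", "B", "C", "D"), 2L,
                                  data.frame(chrom = "chr1", start = 0,
                                             end = 1e4),
                                  c(0.5, 0.3, 0.2), seed = 9L)
  expect_identical(lapply(trees1, write_newick), lapply(trees2, write_newick))
})

test_that("sim_config validates drift, events and pedigrees", {
  expect_error(sim_config("(A:1.5,B:0.1);"), "strictly in")
  expect_error(sim_config("(A:0.1,B:0.1);", n_sites = 0), "positive")
  expect_error(sim_config("(A:0.1,B:0.1);", introgression_events =
    list(list(donor = "X", recipient = "A", chrom = "chr1", start = 1,
              end = 10, alpha = 0.5))), "unknown species")
  expect_error(sim_config("(A:0.1,B:0.1);", introgression_events =
    list(list(donor = "A", recipient = "B", chrom = "chr1", start = 1,
              end = 10, alpha = 1.5))), "alpha")
  expect_error(sim_config("(A:0.1,B:0.1);", hybrid_specs =
    list(list(a = "A", b = "B", pedigree = "F3", count = 1))),
    "unknown pedigree")
})

test_that("introgression blending is a linear mixture confined to the tract", {
  cfg <- sim_config("((A:0.1,B:0.1):0.1,C:0.3);", n_sites = 300L,
                    chromosome_lengths = c(chr1 = 1e5), seed = 3L)
  fr <- simulate_allele_frequencies(cfg)
  ev <- list(donor = "C", recipient = "B", chrom = "chr1",
             start = 1, end = 5e4, alpha = 0)
  expect_equal(apply_introgression(fr, ev)$freq, fr$freq)
  ev$alpha <- 1
  out <- apply_introgression(fr, ev)
  idx <- fr$sites$pos <= 5e4
  expect_equal(out$freq["B", idx], fr$freq["C", idx])
  expect_equal(out$freq["B", !idx], fr$freq["B", !idx])
  # alpha = 0.5 with hand-planted opposite frequencies
  fr2 <- fr
  fr2$freq["B", ] <- 0
  fr2$freq["C", ] <- 1
  half <- apply_introgression(fr2, modifyList(ev, list(alpha = 0.5)))
  expect_equal(unname(half$freq["B", idx]), rep(0.5, sum(idx)))
  expect_error(apply_introgression(fr, modifyList(ev, list(chrom = "chr9"))),
               "no sites")
})

test_that("genotype sampling is binomial with the planted frequency", {
  sites <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "T")
  ft <- structure(list(freq = rbind(S = c(1, 0, 0.5)), sites = sites),
                  class = "freq_table")
  gs <- sample_genotypes(ft, c(S = 1000L), seed = 8L)
  expect_true(all(gs$geno$geno[, 1] == 2L))
  expect_true(all(gs$geno$geno[, 2] == 0L))
  het <- mean(gs$geno$geno[, 3] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 1000))
  expect_true(all(gs$map$is_reference))
})

test_that("hybrid construction obeys Mendelian expectations", {
  n_sites <- 10000L
  g <- rbind(A_1 = rep(0L, n_sites), A_2 = rep(0L, n_sites),
             B_1 = rep(2L, n_sites), B_2 = rep(2L, n_sites))
  gm <- make_geno(g)
  map <- simple_map(gm, c("A", "A", "B", "B"))
  hy <- make_hybrids(gm, map,
                     list(list(a = "A", b = "B", pedigree = "F1", count = 1),
                          list(a = "A", b = "B", pedigree = "BC1_A",
                               count = 1)),
                     seed = 21L)
  f1 <- hy$geno$geno[hy$truth$sample[hy$truth$pedigree == "F1"], ]
  expect_true(all(f1 == 1L))  # forced heterozygosity at fixed differences
  bc <- hy$geno$geno[hy$truth$sample[hy$truth$pedigree == "BC1_A"], ]
  expect_true(all(bc %in% c(0L, 1L)))
  expect_lt(abs(mean(bc == 1L) - 0.5), 3 * sqrt(0.25 / n_sites))
  expect_false(any(hy$map$is_reference[hy$map$sample %in% hy$truth$sample]))

  # parents fixed for the same allele -> F1 homozygous for it
  g2 <- rbind(A_1 = rep(2L, 50), B_1 = rep(2L, 50))
  gm2 <- make_geno(g2)
  hy2 <- make_hybrids(gm2, simple_map(gm2, c("A", "B")),
                      list(list(a = "A", b = "B", pedigree = "F1",
                                count = 1)), seed = 2L)
  expect_true(all(hy2$geno$geno[3L, ] == 2L))
})

test_that("window-tree mixtures are honoured", {
  win <- data.frame(chrom = "chr1", start = seq(0, 99) * 1e4,
                    end = seq(1, 100) * 1e4)
  trees <- simulate_window_trees(c("A", "B", "C", "D"), 1L, win,
                                 c(1, 0, 0), seed = 4L)
  cls <- vapply(trees, quartet_topology, character(1),
                tips = c("A_1", "B_1", "C_1", "D_1"))
  expect_true(all(cls == "12|34"))

  win2 <- data.frame(chrom = "chr1", start = (seq_len(10000) - 1) * 1e3,
                     end = seq_len(10000) * 1e3)
  trees2 <- simulate_window_trees(c("A", "B", "C", "D"), 1L, win2,
                                  c(0.6, 0.3, 0.1), seed = 14L)
  cls2 <- vapply(trees2, quartet_topology, character(1),
                 tips = c("A_1", "B_1", "C_1", "D_1"))
  frac <- c(mean(cls2 == "12|34"), mean(cls2 == "13|24"),
            mean(cls2 == "14|23"))
  se <- sqrt(c(0.6, 0.3, 0.1) * c(0.4, 0.7, 0.9) / 10000)
  expect_true(all(abs(frac - c(0.6, 0.3, 0.1)) < 3 * se))
  expect_error(simulate_window_trees(c("A", "B", "C", "D"), 1L, win,
                                     c(0.5, 0.5, 0.1), seed = 1L),
               "sum to 1")
})

test_that("truth sets round-trip through JSON byte-identically", {
  cfg <- sim_config("((A:0.1,B:0.1):0.1,C:0.3);", n_per_species = 3L,
                    n_sites = 200L,
                    introgression_events = list(list(donor = "C",
                      recipient = "B", chrom = "chr1", start = 1, end = 5e5,
                      alpha = 0.3)),
                    hybrid_specs = list(list(a = "A", b = "B",
                                             pedigree = "F1", count = 1)),
                    seed = 6L)
  sim <- simulate_dataset(cfg)
  sim$truth$window_mixture <- data.frame(window = 1:3, w_sptree = 1,
                                         w_disc1 = 0, w_disc2 = 0)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_truth(sim$truth, p1)
  write_truth(read_truth(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_truth(p1)
  expect_equal(back$hybrids$sample, sim$truth$hybrids$sample)
  expect_equal(back$regions$alpha, sim$truth$regions$alpha)
})
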