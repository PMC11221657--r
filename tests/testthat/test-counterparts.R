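# hand-built f-branch matrix fixture: 3 terminal + 1 internal branch
toy_fbranch <- function(values) {
  m <- values
  class(m) <- c("fbranch", class(m))
  attr(m, "terminal") <- !grepl(",", rownames(m))
  attr(m, "outgroup") <- "O"
  m
}

toy_table <- function(species, counterpart, fb = 0.1) {
  tab <- data.frame(species = species, counterpart = counterpart, fb = fb,
                    tie = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("counterpart_table", class(tab))
  tab
}

test_that("top counterparts take the terminal-branch argmax only", {
  m <- rbind(A = c(A = NA, B = 0.1, C = 0.3),
             B = c(A = 0.2, B = NA, C = 0.05),
             C = c(A = 0.01, B = 0.02, C = NA),
             "A,B" = c(A = NA, B = NA, C = 0.9))  # internal, must be ignored
  tab <- top_counterparts(toy_fbranch(m))
  expect_equal(tab$counterpart[tab$species == "A"], "C")
  expect_equal(tab$counterpart[tab$species == "B"], "A")
  expect_equal(tab$counterpart[tab$species == "C"], "B")
  expect_false("A,B" %in% tab$species)
  # tie broken lexicographically with a warning
  m2 <- rbind(A = c(A = NA, B = 0.3, C = 0.3),
              B = c(A = 0.2, B = NA, C = 0.1),
              C = c(A = 0.1, B = 0.2, C = NA))
  expect_warning(tab2 <- top_counterparts(toy_fbranch(m2)), "tie")
  expect_equal(tab2$counterpart[tab2$species == "A"], "B")
  expect_true(tab2$tie[tab2$species == "A"])
  # all-undefined row dropped with warning
  m3 <- rbind(A = c(A = NA, B = NA, C = NA),
              B = c(A = 0.2, B = NA, C = 0.1),
              C = c(A = 0.1, B = 0.2, C = NA))
  expect_warning(tab3 <- top_counterparts(toy_fbranch(m3)), "dropped")
  expect_false("A" %in% tab3$species)
})

test_that("mutual-pair deduplication removes exactly one per pair", {
  tab <- toy_table(c("A", "B", "C", "D"), c("B", "A", "D", "C"))
  out <- dedupe_mutual_pairs(tab, seed = 1L)
  expect_equal(nrow(out), 2L)
  expect_true(xor("A" %in% out$species, "B" %in% out$species))
  expect_true(xor("C" %in% out$species, "D" %in% out$species))
  # both dedup outcomes occur across seeds
  kept <- vapply(1:20, function(s)
    "A" %in% dedupe_mutual_pairs(tab, seed = s)$species, logical(1))
  expect_true(any(kept) && !all(kept))
  # no mutual pairs -> identity
  tab2 <- toy_table(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(dedupe_mutual_pairs(tab2, seed = 1L), tab2)
})

test_that("basin test edge cases and brute-force agreement", {
  tab <- toy_table(c("A", "B", "C"), c("B", "C", "A"))
  shared <- list(A = "x", B = "x", C = "x")
  res <- basin_permutation_test(tab, shared, n_sim = 500L, seed = 1L)
  expect_equal(res$observed, 3L)
  expect_equal(res$p, 1)
  disjoint <- list(A = "x", B = "y", C = "z")
  res0 <- basin_permutation_test(tab, disjoint, n_sim = 500L, seed = 1L)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p, 1)
  # 4-species fixture vs exhaustive enumeration over 3^4 assignments
  basins <- list(A = c("x"), B = c("x", "y"), C = c("y"), D = c("z"))
  tab4 <- toy_table(c("A", "B", "C", "D"), c("B", "A", "B", "A"))
  res4 <- basin_permutation_test(tab4, basins, n_sim = 20000L, seed = 5L)
  sp <- tab4$species
  shares <- function(x, y) length(intersect(basins[[x]], basins[[y]])) > 0
  grid <- expand.grid(lapply(sp, function(s) setdiff(sp, s)),
                      stringsAsFactors = FALSE)
  counts <- apply(grid, 1L, function(row)
    sum(mapply(shares, sp, as.character(row))))
  p_exact <- mean(counts >= res4$observed)
  expect_lt(abs(res4$p - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000))
  expect_error(basin_permutation_test(toy_table("A", "B"), shared, 10L, 1L),
               "at least two")
})

test_that("distance z-scores follow mean/sd arithmetic", {
  # star-like fixture via a ladder tree with known distances
  tree <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  tab <- toy_table(c("A", "B", "C", "D"), c("B", "A", "A", "A"))
  out <- distance_zscores(tree, tab)
  dA <- c(B = 2, C = 4, D = 4)
  expect_equal(out$z[out$species == "A"],
               (2 - mean(dA)) / sd(dA))
  # ladder tree gives A distances {2, 4, 6}: z = -1 at 2, z = 0 at the mean
  tree2 <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  tab2 <- toy_table(c("A", "B", "C", "D"), c("B", "A", "A", "A"))
  out2 <- distance_zscores(tree2, tab2)
  expect_equal(out2$z[out2$species == "A"], -1)
  tab2b <- toy_table(c("A", "B", "C", "D"), c("C", "A", "A", "A"))
  expect_equal(distance_zscores(tree2, tab2b)$z[1], 0)
  # zero spread -> undefined
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  out3 <- distance_zscores(star, tab2)
  expect_true(all(is.na(out3$z)))
})

test_that("distance permutation test counts tail species by direction", {
  tree <- parse_newick("(((A:0.1,B:0.1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  tab <- toy_table(c("A", "B", "C", "D", "E", "F"),
                   c("B", "A", "D", "C", "F", "E"))
  closer <- distance_permutation_test(tab, tree, n_sim = 2000L, seed = 2L,
                                      direction = "closer")
  farther <- distance_permutation_test(tab, tree, n_sim = 2000L, seed = 2L,
                                       direction = "farther")
  z <- distance_zscores(tree, tab)$z
  expect_equal(closer$observed, sum(z <= -2, na.rm = TRUE))
  expect_equal(farther$observed, sum(z >= 2, na.rm = TRUE))
  expect_true(closer$p > 0 && closer$p <= 1)
  # star tree: no species can be extreme
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  res <- distance_permutation_test(tab, star, n_sim = 500L, seed = 1L)
  expect_equal(res$observed, 0L)
  expect_equal(res$p, 1)
})

test_that("repeat-max-p enumerates dedup resolutions conservatively", {
  basins <- list(A = "x", B = "y", C = "x", D = "z")
  # A and B are mutual; the two dedup outcomes can differ in p
  tab <- toy_table(c("A", "B", "C", "D"), c("B", "A", "A", "A"))
  test_fun <- function(t, s) basin_permutation_test(t, basins,
                                                    n_sim = 2000L, seed = s)
  res <- repeat_max_p(tab, test_fun, n_repeats = 10L, seed = 3L)
  # brute force: evaluate both possible reduced tables with large n_sim
  p_both <- vapply(list(tab[-1L, ], tab[-2L, ]), function(t)
    basin_permutation_test(t, basins, n_sim = 20000L, seed = 99L)$p,
    numeric(1))
  expect_lt(abs(res$p_max - max(p_both)), 0.03)
  expect_length(res$p_values, 10L)
  # no mutual pairs -> all repeats identical up to Monte Carlo error
  tab2 <- toy_table(c("A", "B", "C"), c("B", "C", "A"))
  res2 <- repeat_max_p(tab2, function(t, s)
    basin_permutation_test(t, basins, n_sim = 5000L, seed = s),
    n_repeats = 3L, seed = 1L)
  expect_lt(diff(range(res2$p_values)), 0.05)
  # single repeat reduces to the base test
  res3 <- repeat_max_p(tab2, test_fun, n_repeats = 1L, seed = 5L)
  expect_length(res3$p_values, 1L)
})
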