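#' End-to-end synthetic demonstration of the full pipeline
#'
#' Simulates a five-species genome (four ingroup species A-D plus outgroup O)
#' with a planted C -> B introgression tract and planted A x D F1 / backcross
#' hybrids, then runs every stage: VCF round trip, marker filters,
#' site-pattern statistics, f-branch, counterpart permutation tests, topology
#' weighting and the Dwt region scan, region-overlap permutation test,
#' supervised hybrid calling with diagnostic-SNP profiles, and net-divergence
#' dating on a separate known-split simulation. Every quantity with planted
#' truth is compared to it in the returned report. Fully deterministic given
#' `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, the main artifacts (VCF,
#'   sample map, weights TSV, region BED, counterpart and hybrid reports,
#'   truth JSON) are written there, each with a seed-stamped header.
#' @param verbose print a stage-by-stage summary.
#' @return a named list report (see the vignette for a walkthrough).
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, verbose = FALSE) {
  seeds <- derive_seeds(seed, 10L)
  say <- function(...) if (verbose) cat(..., "\n")
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed)

  ## -- simulate ------------------------------------------------------------
  say("stage simulate: drift-structured genomes with planted truth")
  tract <- list(donor = "C", recipient = "B", chrom = "chr1",
                start = 200001, end = 600000, alpha = 0.5)
  cfg <- sim_config(
    species_tree = paste0("((((A:0.1,B:0.1):0.06,C:0.12):0.06,",
                          "D:0.18):0.05,O:0.35);"),
    n_per_species = 8L, n_sites = 8000L,
    chromosome_lengths = c(chr1 = 1e6, chr2 = 5e5),
    introgression_events = list(tract),
    hybrid_specs = list(list(a = "A", b = "D", pedigree = "F1", count = 2L),
                        list(a = "A", b = "D", pedigree = "BC1_A",
                             count = 2L)),
    basin_map = list(A = c("basin1", "basin2"), B = "basin1", C = "basin3",
                     D = "basin4", O = "basin5"),
    seed = seeds[1L])
  sim <- simulate_dataset(cfg)
  report$truth <- sim$truth

  ## -- genotype IO and filters ----------------------------------------------
  say("stage filter: VCF round trip, MAC filter, LD pruning")
  vcf_path <- file.path(if (is.null(out_dir)) tempdir() else out_dir,
                        "demo.vcf")
  write_vcf(sim$geno, vcf_path)
  geno <- read_vcf(vcf_path)
  stopifnot(identical(geno$geno, sim$geno$geno))
  flt <- mac_filter(geno, min_count = 3L)
  flt <- ld_prune(flt, r2_threshold = 0.6, window_bp = 20000L)
  report$n_sites <- c(simulated = ncol(geno$geno), filtered = ncol(flt$geno))

  ## -- site-pattern statistics ----------------------------------------------
  say("stage dstats: D / Dp / f4-ratio for trio (A, B; C | O)")
  freqs <- species_frequencies(flt, sim$map)
  trio <- c("A", "B", "C", "O")
  jk <- jackknife_test(freqs, trio)
  sums <- site_pattern_sums(freqs, trio)
  report$dstats <- list(D = jk$D, Z = jk$Z, p = jk$p,
                        Dp = as.numeric(dp_statistic(sums)),
                        f4 = as.numeric(f4_ratio(freqs, trio)))

  ## -- f-branch and counterpart tests ---------------------------------------
  say("stage fbranch: branch-resolved gene flow and counterpart tests")
  fb <- f_branch(cfg$species_tree, freqs, outgroup = "O")
  top <- top_counterparts(fb)
  report$fbranch <- list(matrix = fb, counterparts = top)
  basins <- cfg$basin_map
  report$counterpart_tests <- list(
    basin = repeat_max_p(top, function(tab, s)
      basin_permutation_test(tab, basins, n_sim = 10000L, seed = s),
      n_repeats = 10L, seed = seeds[2L]),
    closer = repeat_max_p(top, function(tab, s)
      distance_permutation_test(tab, cfg$species_tree, n_sim = 10000L,
                                seed = s, direction = "closer"),
      n_repeats = 10L, seed = seeds[3L]))

  ## -- topology weighting and the Dwt scan ----------------------------------
  say("stage dwt: window trees, topology weights, consistent regions")
  windows <- data.frame(chrom = "chr1",
                        start = seq(0L, 990000L, by = 10000L),
                        end = seq(10000L, 1000000L, by = 10000L))
  in_tract <- windows$start >= 200000 & windows$end <= 600000
  # group order (A, B, C, D): the planted B~C introgression topology is the
  # (G1,G4)|(G2,G3) pairing, i.e. weight w3
  mixture <- matrix(rep(c(0.7, 0.15, 0.15), nrow(windows)),
                    ncol = 3L, byrow = TRUE)
  mixture[in_tract, ] <- rep(c(0, 0, 1), each = sum(in_tract))
  trees <- simulate_window_trees(c("A", "B", "C", "D"), 3L, windows, mixture,
                                 seed = seeds[4L])
  grp <- lapply(c("A", "B", "C", "D"), function(s) paste0(s, "_", 1:3))
  w <- t(vapply(trees, topology_weights, numeric(3), groups = grp))
  track <- dwt_track(data.frame(windows, w_sptree = w[, 1L],
                                w_disc1 = w[, 3L], w_disc2 = w[, 2L]))
  regions <- consistent_regions(track)
  truth_region <- data.frame(chrom = "chr1", start = 200000, end = 600000)
  recovered <- region_overlap(regions, truth_region)
  report$dwt <- list(track = track, regions = regions,
                     tract_bp = 400000,
                     recovered_bp = recovered,
                     recovered_fraction = recovered / 400000)

  ## -- region-overlap permutation test --------------------------------------
  say("stage overlap: permutation test of recovered vs planted regions")
  report$overlap_test <- overlap_permutation_test(
    truth_region, regions, cfg$chromosome_lengths, n_perm = 2000L,
    seed = seeds[5L])

  ## -- supervised hybrid calling --------------------------------------------
  say("stage hybrids: supervised ancestry, SEs, hybrid calls")
  panel <- build_reference_panel(flt, sim$map, groups = c("A", "D"))
  test_ids <- c(sim$map$sample[sim$map$species %in% c("A", "D")],
                sim$truth$hybrids$sample)
  calls <- lapply(test_ids, function(id) {
    fit <- supervised_ancestry(flt, id, panel)
    se <- bootstrap_se(flt, id, panel, n_boot = 50L, block_sites = 100L,
                       seed = seeds[6L])
    c(list(sample = id), fit["q"], list(se = se),
      call_hybrid(fit$q, se))
  })
  hyb_called <- vapply(calls, function(cl) cl$hybrid, logical(1))
  is_true_hybrid <- test_ids %in% sim$truth$hybrids$sample
  report$hybrids <- list(
    calls = data.frame(sample = test_ids,
                       qA = vapply(calls, function(cl) cl$q[["A"]], 1),
                       qD = vapply(calls, function(cl) cl$q[["D"]], 1),
                       seA = vapply(calls, function(cl) cl$se[[1L]], 1),
                       seB = vapply(calls, function(cl) cl$se[[2L]], 1),
                       hybrid = hyb_called, truth = is_true_hybrid),
    sensitivity = mean(hyb_called[is_true_hybrid]),
    false_positives = sum(hyb_called[!is_true_hybrid]))

  ## -- diagnostic SNP profiles ----------------------------------------------
  say("stage diagnostics: species-diagnostic SNP profiles of hybrids")
  panels <- lapply(c("A", "D"), function(s)
    find_diagnostic_snps(flt, sim$map, s, others = c("A", "D")[c("A", "D") != s]))
  panels <- Filter(function(p) nrow(p) > 0L, panels)
  report$diagnostics <- if (length(panels))
    do.call(rbind, lapply(sim$truth$hybrids$sample,
      function(id) diagnostic_profile(flt, id, panels)))

  ## -- introgression dating -------------------------------------------------
  say("stage date: net-divergence dating on a known-split simulation")
  div <- simulate_divergence_pair(seed = seeds[7L])
  est <- date_introgression(div$geno, div$map, "focal", "donor",
                            div$windows, mu = 1e-6, generation_time = 1,
                            n_boot = 1000L, seed = seeds[8L])
  report$dating <- list(estimate = est, true_t = div$t_gen,
                        covered = est$ci[1L] <= div$t_gen &&
                                  div$t_gen <= est$ci[2L])

  if (!is.null(out_dir)) write_demo_outputs(report, sim, out_dir)
  say("demo complete")
  report
}

# write the demo's main artifacts with seed-stamped headers
write_demo_outputs <- function(report, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("genoflow %s seed=%d",
                 as.character(utils::packageVersion("genoflow")),
                 report$seed)
  write_sample_map(sim$map, file.path(out_dir, "samples.tsv"))
  write_truth(sim$truth, file.path(out_dir, "truth.json"))
  tr <- report$dwt$track
  con <- file(file.path(out_dir, "dwt_track.tsv"), "w")
  writeLines(paste0("#", hdr), con)
  utils::write.table(tr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_bed(report$dwt$regions, file.path(out_dir, "dwt_regions.bed"),
            header = hdr)
  con <- file(file.path(out_dir, "counterparts.tsv"), "w")
  writeLines(paste0("#", hdr), con)
  utils::write.table(report$fbranch$counterparts, con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(file.path(out_dir, "hybrid_calls.tsv"), "w")
  writeLines(paste0("#", hdr), con)
  utils::write.table(report$hybrids$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(out_dir)
}
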