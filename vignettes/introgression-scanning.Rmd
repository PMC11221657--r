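---
title: "Detecting, localizing and dating introgression with genoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, localizing and dating introgression with genoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

genoflow is a toolkit for studying hybridization in multi-species SNP
datasets at two time scales: ancient gene flow between lineages (detected
from site patterns and gene-tree discordance) and contemporary hybridization
between co-occurring species (detected from individual ancestry profiles).
The motivating setting is a genus of closely related fish species sampled
across river and lake drainage basins, with whole-genome genotype calls, a
rooted species tree, and window gene trees — but nothing in the package is
specific to that system. This vignette is the package's account of the
methods: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not show.

## The data model

Genotypes are diploid dosages of the alternate allele (0/1/2, `NA` for a
missing call) at biallelic SNPs (`geno_matrix`). A sample map assigns each
individual a species, a reference-panel flag (confidently non-hybrid
individuals used to estimate species allele frequencies), and a set of
drainage basins. Two marker-level filters mirror standard practice and are
applied before frequency-based analyses:

* `mac_filter()` removes sites with minor-allele count below 3, so every
  retained variant is seen in more than one individual (guarding against
  genotyping error);
* `ld_prune()` removes sites whose dosage correlation exceeds r² = 0.6
  with a retained site within 20 kb, by a deterministic left-to-right
  greedy scan. r² is the squared Pearson correlation of genotype dosages
  (composite LD) — appropriate when phase is unknown; missing genotypes are
  excluded pairwise, and zero-variance pairs count as r² = 0. The greedy
  keep-first order makes the filter reproducible and idempotent.

## Topology weighting and the Dwt scan

For four groups of haplotypes (in practice: four species, each with several
sampled individuals) a window gene tree induces, for every one-tip-per-group
subtree, one of three quartet resolutions: the species-tree pairing or one
of two discordant pairings. `topology_weights()` reports the fraction of
subtrees supporting each resolution — exhaustively when the number of
combinations is at most `max_exact` (default 10,000), otherwise by Monte
Carlo with a fixed seed. Star (unresolved) subtrees contribute 1/3 to each
weight so the weights always sum to one; dropping them instead would leave
windows on polytomous trees under-normalized. Quartets are classified by the
four-point condition on unit-branch-length path distances, which is exact
for trees and cheap to vectorize over thousands of combinations.

Under incomplete lineage sorting (ILS) alone the two discordant topologies
are equally weighted on average. Introgression between non-sister species
inflates one of them — the designated introgression topology `disc1`. The
scan statistic combines both departures:

Dwt = ((disc1 − disc2) / (disc1 + disc2)) ×
((max(sptree, disc1, disc2) − sptree) / (max(sptree, disc1, disc2) + sptree))

The first factor measures asymmetry between the discordant topologies; the
second is zero whenever the species tree carries the maximum weighting and
grows as the species tree is displaced. Dwt is 0 when the species tree
dominates, 1 when `disc1` is fully supported, −1 when `disc2` is. When
`disc1 + disc2 = 0` the first factor is taken as 0 (pure species-tree
windows), and all-zero (data-empty) windows are undefined and propagate as
`NA`.

`consistent_regions()` extracts maximal runs of contiguous windows with
Dwt within `tol` of 1.0 spanning at least 50 kb. Strict runs are used: a
single sub-threshold window breaks the run. `tol` defaults to 1e-9 (exact
support); a looser tolerance is exposed for noisy weightings, and run
strictness is a deliberate choice — a merge-gap parameter would admit
regions the scan does not in fact support consistently.
`overlap_permutation_test()` asks whether two comparisons' region sets
co-occur more than expected: the second set's intervals are independently
re-placed uniformly at random within their chromosome (lengths preserved,
overlaps among placed intervals allowed). This null is simple and
symmetric; a circular-rotation null would preserve inter-interval spacing
but anchor the permutation to an arbitrary origin. The p-value uses the
add-one estimator (k+1)/(N+1), which never reports zero.

## Site-pattern statistics

For a trio arrangement (((P1,P2),P3),O) with per-group alternate-allele
frequencies, `site_pattern_sums()` accumulates the frequency-weighted
ABBA/BABA/BBAA sums, and:

* `d_statistic()`: D = (ABBA − BABA)/(ABBA + BABA), the classic test of
  asymmetric allele sharing; antisymmetric in P1/P2.
* `jackknife_test()`: delete-one block jackknife over 20 contiguous site
  blocks (block structure is a package choice; contiguous blocks absorb
  local LD), Z = D/SE, two-sided normal p-value. Identical blocks give
  SE = 0, flagged as degenerate rather than divided through.
* `dp_statistic()`: Dp = (ABBA − BABA)/(ABBA + BBAA), an estimate of the
  introgressed proportion of the genome; reported clamped to [0, 1] with a
  flag, since drift noise can push the raw value slightly negative.
* `f4_ratio()`: the admixture fraction by donor substitution — the observed
  ABBA − BABA excess divided by the excess expected if P2 were replaced by
  the donor P3. This estimator needs no within-P3 haplotype split, at the
  cost of assuming the donor's own drift since the event is small. The
  denominator contains the donor frequency squared, which finite panels
  inflate by their sampling variance (a ~25% downward bias on the ratio at
  8 diploid donors); when allele counts accompany the frequency table (as
  `species_frequencies()` provides) the squared term is debiased by the
  unbiased sampling-variance estimate p(1 − p)/(n − 1).

`f_branch()` summarizes many correlated f4-ratios on a rooted species tree:
for each branch b and each candidate donor tip C outside the clade of b and
its sister, fb(C) is the minimum over recipients B in clade(b) of the
median over A in the sister clade of f4(A, B; C, O), floored at 0. The
min/median orientation makes fb conservative: a high value requires every
recipient in the clade to show the signal against a majority of sister
backgrounds. The orientation is validated functionally — planted gene flow
must localize to the correct (branch, donor) cell, which the validation
suite asserts.

Window-tree counterparts of these tests: `dct_test()` is a 1-df chi-squared
test of the two discordant topology counts against the ILS-only equal
expectation, and `blt_test()` compares sister-pair tip distances between the
two discordant window classes by one-sided rank sum — under introgression
the introgressant pair's windows coalesce more recently, so their distances
are stochastically smaller. The rank-sum form is deliberately simple and
distribution-free; classes with fewer than 5 windows are skipped with a
flag rather than tested.

## Counterpart permutation tests

To ask what predicts gene flow without pseudo-replicating correlated
f4-ratios, each species is reduced to its single strongest partner: the tip
with the highest f-branch against the species' terminal branch
(`top_counterparts()`; internal branches are excluded so only species pairs
are compared; ties break lexicographically with a warning). When two
species pick each other the pair reflects one event, so one of the two is
dropped at random (`dedupe_mutual_pairs()`), and because that choice is
random the whole test is repeated ten times with the highest p-value
recorded (`repeat_max_p()`) — conservative over the dedup resolution.

Two nulls are then simulated, 100,000 draws each by default, with each
species drawing a uniformly random counterpart from the other tested
species. `basin_permutation_test()` counts counterparts sharing at least
one drainage basin; `distance_permutation_test()` counts counterparts whose
coalescent distance is extreme for that species (z ≤ −2 closer, z ≥ 2
farther, z-scores from the species' distances to all tested species).
p-values are raw proportions of simulations at or beyond the observed
count. Uniform draws are one reading of a counterpart null; a
sharing-probability-weighted draw is conceivable but needs a model of the
basin-occupancy process, which the package does not assume. Species whose
terminal branch has no defined donors (those adjacent to the root of the
ingroup) are dropped with a warning rather than failing the whole
protocol, since real rooted trees always contain such species.

## Supervised ancestry and hybrid calling

With reference allele frequencies f fixed (`build_reference_panel()`;
frequencies clamped to [1e-4, 1 − 1e-4] so fixed differences keep
likelihoods finite), a test individual's ancestry proportions q maximize
the binomial likelihood of its dosages at p = Σ q_k f_k, by EM on the
simplex (`supervised_ancestry()`). The EM log-likelihood is non-decreasing
— asserted per iteration in the tests. Standard errors come from a
moving-block bootstrap (`bootstrap_se()`, 100 replicates of 200-site
blocks; blocks absorb local LD, and replicates warm-start from the
full-data estimate). An individual is called a hybrid when at least two
components have q_k − se_k ≥ 0.1 (`call_hybrid()`) — "lower end of the
standard error" is read as one standard error below the point estimate;
the 0.1 cutoff targets hybrids up to second-generation backcrosses.
`unsupervised_admixture()` fits Q and F jointly by EM with five seeded
restarts, used to probe hybrid-origin populations: a 50/50 ancient mixture
shows ~0.5/0.5 at K = 2 and becomes its own component at K = 3.

Species-diagnostic SNPs (`find_diagnostic_snps()`) are sites fixed in the
focal species' reference individuals for an allele at frequency below 0.1
in every other species' reference individuals. `diagnostic_profile()`
reports, per panel, the fractions of homozygous-diagnostic, heterozygous
and homozygous-other sites: F1 hybrids are near-fully heterozygous on both
parental panels; backcrosses shift toward homozygous-diagnostic on the
recurrent parent's panel by the Mendelian 50/50 expectation.

## Dating introgression

`nucleotide_diversity()` is the per-site unbiased heterozygosity
2p(1−p)·n/(n−1) averaged over a window's accessible sites; `dxy()` the
average between-taxon mismatch rate pA(1−pB) + pB(1−pA). Windows are
200-SNP blocks (`snp_windows()`). `assign_window_sister()` selects windows
where every focal haplotype's nearest candidate clade agrees — the windows
attributable to one donor. The date is the net-divergence estimator
T = max(0, (mean Dxy − mean π_donor)/(2μ)) generations
(`introgression_time()`), with the donor's diversity in the same windows
standing in for the ancestral diversity at the time of gene flow; the π
source is exposed as an argument because donor, recipient, or pair-mean
conventions all appear in practice. μ and generation time are required
inputs with no defaults — they are organism-specific assumptions, not
estimable from the data at hand. Confidence intervals are 2.5/97.5
percentiles of window-resampled estimates (`bootstrap_ci()`, 1,000
replicates).

## The synthetic-data generator

All validation rests on `sim_config()`/`simulate_dataset()`, which emulate
the statistical structure the analyses assume, with full knowledge of the
truth:

* Allele frequencies drift down the species tree by Balding-Nichols steps —
  Beta-distributed with mean equal to the parent frequency and variance
  p(1−p)F per branch. This gives tunable, tree-structured divergence
  without coalescent machinery; ancestral frequencies are Uniform(0.05,
  0.95) so site-pattern sums stay informative.
* Introgression tracts blend donor into recipient frequencies linearly with
  admixture fraction α — the deterministic imprint of a pulse.
* Genotypes are Binomial(2, p); F1 hybrids take one allele per site from a
  random individual of each parent, backcrosses cross an internal F1 to the
  recurrent parent. Sites are unlinked.
* Window gene trees come from controlled topology mixtures
  (`simulate_window_trees()`), each species expanded to a clade of its
  individuals.
* `simulate_divergence_pair()` adds a known-split toy model for dating:
  shared ancestral polymorphism plus lineage-specific fixed differences at
  rate μT per site, so E[Dxy − π] = 2μT by construction.

What passing the synthetic suite shows: the estimators recover the
quantities they target under the model they assume, at realistic noise
levels, and the permutation machinery is correctly calibrated. What it does
not show: robustness to linkage (sites here are exchangeable; block
jackknife and block bootstrap exist precisely because real data are not),
to non-equilibrium demography, to selection, or to reference-panel
misassignment. The generator has no recombination map, so tract boundaries
are window-aligned and crisp in a way real introgressed haplotypes are not.

## Calibration and problem sizes

The validation suite checks, at desk scale chosen by the package: exact
analytic Dwt values; exact-enumeration topology weights against a
brute-force bipartition oracle and Monte Carlo agreement within 0.01 at
10^5 draws; uniformity of null p-values (Kolmogorov-Smirnov, 200 replicates
each) for the discordance count test (500-window counts), the block
jackknife (5,000-site drift-only frequencies), the region-overlap
permutation (20 × 10 kb intervals on a 1 Mb chromosome, 299 permutations),
and both counterpart tests (15 species, 2,000 null draws). The counterpart
statistics are small counts, so their calibration uses the randomized
probability integral transform against the test's own simulated null —
exactly Uniform(0, 1) for a discrete statistic, where the plain p-value is
only super-uniform; the user-facing tests keep the raw-proportion p-value.
Parameter recovery uses 5 × 10^4 sites for the f4-ratio (α within ±0.05),
10^4 sites for pedigree ancestry (±0.05), 2 × 10^4 for f-branch
localization; hybrid calling is validated end to end on 24 reference and 13
hybrid individuals at 4,000 sites; dating coverage on 200 replicates of 40
× 250-site windows. `run_demo()` wires every stage together on a
five-species, 8,000-site genome in well under a minute.

## Interfaces

The package is function-first: an analysis is an R script composing the
stages, and `run_demo()` is the canonical template. Files use standard
text formats throughout — VCF v4.2 (GT-only) and a TSV sample map, newick
trees, BED regions, bedGraph-style weight tracks, TSV reports, JSON truth
sets — so every artifact can be inspected or produced by other tools.
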