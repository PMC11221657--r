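# genoflow

Detecting, localizing and dating introgression, and calling recent hybrids,
from multi-species SNP data.

When closely related species meet — in a shared river basin, or because one
was introduced for aquaculture — they may hybridize. Gene flow leaves two
distinct signatures: ancient introgression shows up as asymmetric allele
sharing and distorted gene-tree frequencies along the genome, while recent
hybridization shows up in individual genomes as mixed ancestry and
heterozygous runs of species-diagnostic markers. genoflow implements both
ends of this analysis for population geneticists working with whole-genome
genotype matrices (VCF), a rooted species tree, and per-window gene trees
(newick), plus a seeded synthetic-data generator with known truth that
validates every stage.

## Methods at a glance

* **Topology weighting and the Dwt scan.** For four groups, a window gene
  tree's topology weights `(w_sptree, w_disc1, w_disc2)` are the fractions
  of one-tip-per-group subtrees supporting each quartet resolution. The
  scan statistic

  `Dwt = ((disc1 − disc2)/(disc1 + disc2)) ·
  ((max(sptree, disc1, disc2) − sptree)/(max(sptree, disc1, disc2) + sptree))`

  is 0 where the species tree carries the highest weighting, 1 where the
  putative introgression topology `disc1` is fully supported, and −1 where
  the other discordant topology is. Runs of Dwt = 1.0 windows spanning
  ≥ 50 kb become candidate introgressed regions, and a permutation test
  (random re-placement of intervals within chromosomes) assesses overlap
  between region sets from different comparisons.
* **Site-pattern statistics.** ABBA–BABA D with block-jackknife Z and
  p-value, the introgressed-proportion statistic
  `Dp = (ABBA − BABA)/(ABBA + BBAA)`, the donor-substitution f4-ratio
  estimate of the admixture fraction, and the f-branch matrix
  `fb(branch, donor) = max(0, min over recipients of the median over sister
  backgrounds of f4(A, B; C, O))` which localizes gene flow on the species
  tree. Window-tree analogues: a discordance count test (1-df chi-squared
  against the ILS-only 50/50 expectation) and a branch-length rank-sum test.
* **Counterpart permutation tests.** Each species is paired with the tip
  giving its highest f-branch; mutual pairs are deduplicated at random (ten
  repeats, highest p recorded). Permutation nulls with uniformly random
  counterparts test whether top counterparts share drainage basins, or are
  phylogenetically closer/farther (|z| ≥ 2 on coalescent distances), more
  often than chance.
* **Hybrid detection.** Supervised admixture by EM against a reference
  panel, moving-block-bootstrap standard errors, and the rule that an
  individual is a hybrid when ≥ 2 ancestry components have `q − se ≥ 0.1`.
  Species-diagnostic SNP panels (fixed in the focal species, < 0.1
  elsewhere) give hom/het/hom profiles separating F1s from backcrosses.
  Unsupervised EM admixture (K = 2, 3) probes hybrid-origin populations.
* **Dating.** Window-wise π and Dxy give the net-divergence date
  `T = (mean Dxy − mean π_donor)/(2μ)` generations over gene-tree-assigned
  windows, with a window-bootstrap percentile CI.

## Worked example

`run_demo()` simulates a five-species genome (four ingroup species A–D plus
outgroup O) with a planted C → B introgression tract (chr1:200–600 kb,
α = 0.5) and planted A × D hybrids, then runs the whole pipeline:

```r
library(genoflow)
rep <- run_demo(seed = 7, out_dir = "demo_out")

rep$dwt$recovered_fraction
#> [1] 1
rep$overlap_test$p
#> [1] 0.01649175
rep$fbranch$counterparts
#>   species counterpart         fb   tie
#> 1       A           C 0.00000000  TRUE
#> 2       B           C 0.14595659 FALSE
#> 3       C           D 0.09596265 FALSE
rep$hybrids$sensitivity; rep$hybrids$false_positives
#> [1] 1
#> [1] 0
rep$dating$estimate$t_years; rep$dating$covered
#> [1] 4960.447
#> [1] TRUE
```

Reading the output: the Dwt scan recovered 100% of the planted tract as
≥ 50 kb Dwt = 1.0 regions, and the recovered regions overlap the truth more
than randomly re-placed regions would (p ≈ 0.016). The f-branch counterpart
of recipient B is the planted donor C, with fb ≈ 0.15 — the genome-wide
dilution of a 0.5 admixture pulse covering about a quarter of the genome.
All four planted hybrids (two F1, two first-generation backcrosses) are
called with no false positives among the 16 pure A/D individuals, and the
net-divergence date of a separate known-split simulation (5,000
generations) is estimated at ≈ 4,960 years with a bootstrap CI bracketing
the truth. Warnings about counterpart ties are expected: species without
gene flow have f-branch rows floored at zero.

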