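Package: genoflow
Title: Genome-Wide Introgression Scanning, Hybrid Detection and Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing ancestral introgression and
    recent hybridization from multi-species SNP data. Implements topology
    weighting over window gene trees and the derived Dwt scan statistic with
    extraction of consistently introgressed regions and a region-overlap
    permutation test; ABBA-BABA site-pattern statistics (D, Dp, f4-ratio) with
    block-jackknife significance and the branch-resolved f-branch matrix;
    discordance count and branch-length tests on window trees; permutation
    tests for drainage-basin sharing and phylogenetic distance of top gene-flow
    counterparts; supervised and unsupervised admixture estimation by EM with
    block-bootstrap standard errors, hybrid calling, and species-diagnostic SNP
    profiling; window-wise nucleotide diversity and divergence with
    net-divergence introgression dating. Includes a synthetic-data generator
    (drift-structured allele frequencies, planted introgression tracts, F1 and
    backcross hybrids, controlled gene-tree mixtures) with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
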