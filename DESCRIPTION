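Package: trioscan
Title: Two-Locus Allele-Pair Imbalance Scans in Pedigreed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects epistatic interactions (Dobzhansky-Muller type allele
    incompatibilities) from genotypes of parent-offspring trios, without any
    phenotype. For every pair of markers on different chromosomes a chi-square
    style statistic compares the observed 3x3 joint genotype table of the
    offspring against the table expected under Mendelian transmission, after a
    per-marker correction for segregation distortion and other single-locus
    confounders. Significance is assessed with marker-pair-specific permutation
    nulls built from pseudo-offspring (genomes re-assembled from the gametes the
    parents could have transmitted), with Benjamini-Hochberg FDR control.
    Includes a two-step genome scan (LD-block representatives, then marker-level
    fine mapping), a hypergeometric congruence score comparing interaction
    profiles of loci, and a gene-dropping pedigree simulator (founder lines,
    recombination, genotyping error, missingness, planted lethal two-locus
    incompatibilities) used for null calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
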