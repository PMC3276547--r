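---
title: "Detecting two-locus allele-pair imbalances from trio genotypes"
author: "trioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting two-locus allele-pair imbalances from trio genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The problem

Dobzhansky–Müller incompatibilities are deleterious interactions between
alleles at different loci that are individually harmless; in their extreme
form a particular two-locus genotype combination is embryonic lethal. Such
epistatic effects leave a footprint in a pedigreed population even when no
phenotype is measured: certain genotype *combinations* are rarer (or, for
beneficial interactions, more common) among surviving offspring than
Mendelian transmission from their parents predicts. `trioscan` detects this
footprint from genotyped parent–offspring trios in diploid, biallelic SNP
data — for example an outbred heterogeneous stock derived from a small set of
inbred founder lines, where the pedigree is recorded.

The unit of information is the **trio**: a genotyped child with two genotyped
parents. Everything the method does is conditional on the parental genotypes,
which is what protects it against population structure: each trio carries its
own private null expectation.

## The statistic

Genotypes are coded as minor-allele dosage $G \in \{0, 1, 2\}$. For a trio
$t$ and marker $m$, Mendelian transmission gives the child's genotype
distribution $E_{tm} = (P(0), P(1), P(2))$ as a function of the two parental
dosages (each parent transmits either of its two alleles with equal chance).
A trio contributes at a marker only when all three members are called and the
child is Mendelian-consistent with its parents; inconsistent calls — almost
certainly genotyping errors — are masked for that trio at that marker so that
a single bad call can never force an expected probability of zero onto an
observed genotype.

**Correction for single-locus confounders.** Segregation distortion,
viability selection on single loci, genotyping artefacts and drift all shift
single-marker genotype frequencies away from Mendelian expectation without
any interaction being involved. Following the classical two-step recipe, each
trio's expected 3-vector is multiplied by the per-marker ratio of sample-wide
observed to sample-wide expected genotype counts, then renormalized to sum
to one. A single pass of these two steps leaves a second-order mismatch:
renormalization perturbs the sample-wide sums again whenever trios have
heterogeneous parental genotypes. `normalized_expected()` therefore
*alternates* the two steps — iterative proportional fitting on the
trios × genotype-classes table, independently per marker — until the
sample-wide expected counts equal the observed counts (tolerance $10^{-9}$
on the scaling factors, cap 100 iterations). Convergence is guaranteed
because the observed genotype assignment is itself a feasible table. The
one-pass primitives (`correction_factors()`, `correct_and_normalize()`)
remain available.

**Joint tables and the score.** For a marker pair $(a, b)$ on *different
chromosomes* (same-chromosome pairs are excluded to keep local linkage
disequilibrium out of the picture), over the trios usable at both markers:

$$O_{jk} = \#\{t : G_{ta} = j,\ G_{tb} = k\}, \qquad
  E_{jk} = \sum_t E_{ta}(j)\, E_{tb}(k),$$

the expected table being the per-trio product of marginals — independence of
the two loci is exactly the no-epistasis null. The pair imbalance statistic
is the $\chi^2$-style score

$$S = \sum_{j,k:\,E_{jk}>0} \frac{(O_{jk} - E_{jk})^2}{E_{jk}}.$$

Cells with $E_{jk} = 0$ contribute nothing; after the masking above they
force $O_{jk} = 0$, so the convention resolves only the $0^2/0$ case.

$S$ is *not* referred to a $\chi^2$ distribution: its null distribution
shifts with minor allele frequency (low-MAF pairs concentrate at smaller
values), which would make tail probabilities MAF-dependent.

## Permutation nulls from pseudo-offspring

For each trio and marker, the four genotypes the child could have inherited
(the 2 × 2 transmitted-allele combinations, duplicates kept) are equally
likely under the null. A **pseudo-offspring** draws one of the four at every
usable marker, independently across markers and trios — a genome the child
could have had if loci assorted independently. For each marker pair, $B$
pseudo-offspring cohorts are drawn and the *entire* statistic pipeline
(including the distortion correction, recomputed from the pseudo data) is
re-run on each, so observed and null statistics are exchangeable by
construction. The p-value is the add-one smoothed exceedance fraction

$$p = \frac{1 + \#\{S^{(b)} \ge S_{\mathrm{obs}}\}}{1 + B},$$

with ties counted against the observed score (conservative). The raw
fraction is available via `smooth = FALSE`. Benjamini–Hochberg q-values are
computed across all screened pairs. Each pair owns an RNG stream derived
from the global seed and the two marker ids, so results do not depend on the
order (or parallelisation) of pair evaluation, and pseudo-offspring are
drawn independently per pair — the null is deliberately marker-pair
specific.

## The two-step genome scan

Testing every marker pair with permutations is wasteful when nearby markers
are in strong LD. `trio_scan()` therefore:

1. partitions each chromosome into **LD blocks** by greedy left-to-right
   chaining: the current block grows while the adjacent-marker dosage
   $r^2$ (computed on parents only — children are correlated with their
   parents) stays at or above `r2_threshold` (default 0.8);
2. picks one **representative** per block, uniformly among the markers with
   the block's minimum number of missing calls;
3. tests all inter-chromosomal representative pairs (statistic + permutation
   p-value + BH q-value), flagging pairs with $q \le$ `fdr_cutoff`
   (default 0.25 — screening is deliberately permissive);
4. `fine_map()` then re-tests *all* cross-block marker pairs inside each
   significant block pair and reports the minimum-p marker pair per block
   pair. Fine-map p-values are ranking scores, not calibrated significance
   levels: the tested pairs were selected because their blocks showed a
   signal, and markers within a block are correlated, so no multiplicity
   correction is attached to them.

The greedy adjacent-$r^2$ block rule is a deliberate simplification of
haplotype-based block finders: it is deterministic, testable, and block
granularity only affects how coarsely the screen tiles the genome, not the
test itself.

## Congruence of interaction profiles

Loci bridging the same pair of redundant pathways should share interaction
partners. For two loci with partner sets $A$ and $B$ (interactions called at
a permissive p-value cutoff) in a universe of $U$ tested loci, the
congruence score is $-\log_{10}$ of the hypergeometric upper tail
$P(X \ge |A \cap B|)$ with population $U - 2$, draws $|A|$ and successes
$|B|$. The two focal loci, and any direct interaction between them, are
removed from the universe and from each other's partner sets first — a
shared direct edge should not inflate the congruence of its own endpoints.

## The pedigree simulator

`sim_trio_dataset()` generates the synthetic study conditions used
throughout the tests, emulating a heterogeneous stock:

* **8 inbred founder lines**, one haplotype per chromosome per line (alleles
  i.i.d. Bernoulli(0.5) per marker), **40 founders** homozygous for their
  line's haplotypes, lines assigned round-robin;
* **3 generations of random mating**, ~167 children each (fathers drawn
  from the previous generation's males, mothers from its females), giving
  ~500 genotyped trios — a size at which a full screen with $B = 200$
  permutations runs in minutes on one CPU;
* **5 chromosomes × 40 markers**, inter-marker crossover probability 0.05;
  gametes follow a Markov walk (random starting haplotype, switch with the
  interval's crossover probability);
* optional **genotyping errors** (uniform among the alternatives consistent
  with the individual's trio contexts, so no Mendelian inconsistencies are
  created), **missingness** (i.i.d. or a copied mask), and a planted
  **two-locus lethal incompatibility**: children whose genotype combination
  at the two loci equals the lethal cell are rejected with probability $s$
  and their gametes resampled (capped at 10,000 attempts, after which the
  simulator errors naming the child — this happens exactly when a fixed
  mating can only produce lethal offspring).

Because marker assortment is independent apart from within-chromosome
linkage, an unplanted simulation contains no true interactions: it is the
null-calibration engine. What it does *not* emulate: coalescent founder
history, crossover interference, sex chromosomes, batch effects, or
non-random missingness; calibration on it demonstrates correctness of the
statistical machinery, not robustness to every artefact of real genotyping.

### Choosing a plantable effect

With inbred founders and a fixed pedigree, fully lethal ($s = 1$) selection
terminates only for the minor/minor homozygote cell $(2,2)$ *and* disjoint
carrier line sets (no founder line carries both derived alleles — which is
also the Dobzhansky–Müller premise). Any other lethal cell admits parent
pairs whose every gamete combination is lethal: e.g. for a (het, het) lethal
cell, opposite-homozygote parents at both loci can produce nothing else.
The default planted fixture therefore pins `planted_line_carriers = 3` of 8
lines at each locus (founder MAF 0.375, drifting toward ~0.3 under
selection) with disjoint carrier sets and lethal cell $(2,2)$.

Power at this configuration is intrinsically modest: the planted signal is
approximately the expected count of the lethal cell,
$n\,p_a(2)\,p_b(2) \approx 500 \times 0.1^2 \approx 5$, part of which the
single-marker correction absorbs (selection also depletes the single-locus
homozygote frequencies), while the maximum of ~16,000 null pair statistics
is in the twenties. A recessive–recessive lethal at moderate MAF is
therefore detected as a clear zero-cell signature (the observed table's
lethal cell is empty in every replicate) and an elevated score, but it is
*not* reliably the single top-ranked pair genome-wide at 500 trios — that
would require either substantially more trios, stronger allele frequencies,
or dominance of the incompatibility. The acceptance suite reports the honest
top-1 rate and rank distribution.

## Numerical choices and edge cases

* **Missing sentinel** is R's `NA_integer_`; all consumers mask explicitly.
* **Minor-allele assignment** (PED input): the rarer allele among non-missing
  calls; on an exact tie the lexicographically smaller base is the major
  allele. The package TSV dialect stores the assignment explicitly and
  round-trips exactly.
* **0/0 correction factors** are defined as 1 (no information; the factor
  multiplies a zero anyway). An observed genotype with zero Mendelian
  expectation is an internal-consistency error — it cannot occur once
  inconsistent trios are masked.
* **IPF boundary cases**: when a genotype class can be matched only by
  driving some trios' probabilities to 0 (common at very small trio counts
  with distorted counts), the fixed point lies on the boundary of the
  simplex and convergence degrades from geometric to $O(1/\text{iteration})$;
  the iteration cap then leaves a small residual. At the package's standard
  study sizes (hundreds of trios, MAF-filtered markers) the fixed point is
  interior and the residual is below $10^{-6}$.
* **Minimum pair-usable trios** (default 20): pairs with fewer jointly
  usable trios are skipped with a logged reason — 3 × 3 tables built from a
  handful of trios are uninformatively unstable.
* **Tie-breaks**: permutation ties count against the observed score;
  fine-map winners with equal p are broken by larger $S$; representative
  ties (equal missingness) are broken uniformly at random under the global
  seed.
* **q vs p**: BH q-values are step-up adjusted, hence always $\ge$ their
  p-values; the scan asserts this.

## Problem sizes used in the validation suite

The automated checks run, on one CPU: the exact transmission table (6
combinations); brute-force oracle equivalence on 25 random 5-trio fixtures;
conservation and the correction fixed point on the full ~500-trio null
fixture; calibration of permutation p-values on 600 randomly subsampled
inter-chromosomal representative pairs at $B = 200$ (KS uniformity at
$\alpha = 0.01$, type-I error at nominal 0.05 inside the exact binomial 99%
interval); 20 planted-lethal replicates (zero-cell rate, genome-wide rank);
10,000 pseudo-offspring draws from het × het parents; and 20/10 randomized
comparisons of BH and congruence against formula/enumeration oracles.

## Limitations

* Power against recessive incompatibilities at moderate MAF is limited at
  ~500 trios (see above); the method's strength at this scale is the
  zero-cell signature and block-level localization.
* Fine-map p-values rank, they do not test.
* The X chromosome is not modelled (no sex-aware transmission); exclude it
  during QC.
* Only biallelic markers and trio (not larger family) information are used.
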