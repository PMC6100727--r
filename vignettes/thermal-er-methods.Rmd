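---
title: "Models and methods behind thermoevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thermoevolve)
```

# The experimental design the package models

`thermoevolve` analyses replicated evolve-and-resequence (E&R) experiments
with pooled sequencing: a founder population is split into replicate cages,
evolved for tens of generations under a new (here: hot) environment, and the
ancestral and evolved populations are sequenced as pools. Allele frequencies
are estimated from read counts, so every observed frequency carries binomial
sampling noise on top of real genetic drift and selection. The default
parameters throughout the package mirror a Drosophila thermal-selection
design: five replicates, roughly 60 non-overlapping generations, an
effective population size near `Ne = 219`, Pool-Seq coverage around 80x, and
a site-frequency spectrum with mean minor-allele frequency 0.14. Two
large-effect loci starting from intermediate frequencies (0.44 and 0.20) play
a special role as the focal selection targets.

# Wright-Fisher substrate

Selection is additive with genotype fitnesses `1 : 1 + s/2 : 1 + s`
(dominance fixed at 0.5). One generation applies the deterministic update

```
p' = p * (p*(1+s) + (1-p)*(1+s/2)) / (1 + s*p)
```

followed by binomial sampling of `2*Ne` gametes (`wf_step()`), the standard
forward-time order of events. With `s = 0` the update is pure drift, a
martingale with per-generation variance `p(1-p)/(2Ne)`; 0 and 1 are
absorbing. Iterating the deterministic update reproduces the worked anchors
of the package: a selection coefficient of 0.07 carries an allele from
frequency 0.44 to about 0.86 in 60 generations, and 0.06 carries 0.20 to
about 0.59. Pool-Seq noise is one further binomial draw of reads at the true
frequency (`pool_sample()`); frequency estimation after pooling is unbiased
at any depth.

Because the analysis operates on gamete frequencies, neutral simulations use
binomial sampling of `2*Ne` gametes rather than an explicit diploid
individual model; for the quantities handled here (frequency moments,
temporal variance) the two are equivalent.

# The replicated CMH scan and its calibration

Concordant frequency change across replicates is tested with the
Cochran-Mantel-Haenszel statistic over K replicate strata, each stratum being
the 2x2 table of minor/major read counts in the ancestral versus evolved
sample. The statistic uses hypergeometric means and variances per stratum and
no continuity correction — Pool-Seq counts are large and the correction only
costs power. `cmh_test()` matches `stats::mantelhaen.test(correct = FALSE)`
to ten significant digits; the package's own vectorised implementation is
what the scan uses, since millions of SNPs are tested at once.

A crucial point: the CMH null hypothesis is *no change beyond sampling
noise*. Genetic drift over tens of generations at `Ne` of a few hundred is
real change, so under a drift-only experiment the scan's p-values are far
from uniform — small p-values are common without any selection. That is why
significance is not read from the chi-square distribution but calibrated by
simulation: `calibrate_fpr()` evolves neutral SNP sets matched to the
empirical starting-frequency distribution and SNP count through the same
number of generations at the estimated `Ne`, adds Pool-Seq noise at the
experimental coverage, recomputes CMH p-values, and reports the empirical
false-positive rate

```
FPR(theta) = mean over runs of #{neutral p <= theta} / #{empirical p <= theta}
```

Thresholds with no empirical discovery report `NA` rather than zero. When
the empirical data are themselves neutral this ratio is ~1 at any threshold,
which the test suite checks. The uniformity property of the CMH p-values is
checked under a sampling-only design (drift disabled by an enormous `Ne`),
the statistically correct null of the test.

Two practical devices from the experimental design are provided:
`split_ancestral()` multinomially partitions pooled ancestral reads into K
pseudo-replicates so the ancestral side matches the evolved replication, and
`conservative_merge()` keeps, per SNP, the least significant of several
mapper tracks, trading power against mapper-specific artefacts. SNP calling
requires per-sample coverage in `[5, 500]` and at least one minor-allele read
in *every* sample (`snp_filter()`).

# Temporal Ne estimation

`estimate_ne()` uses the standardised temporal variance of allele frequency
change under two-stage Pool-Seq sampling in which the sequenced individuals
are part of the breeding population (plan I). Per SNP the squared change
`(x - y)^2` is standardised by `z(1-z)`, `z` the mean of the two observed
frequencies. Two design choices matter:

* **Ratio of sums, not mean of ratios.** Squared changes (after subtracting
  the per-SNP sampling variance `p(1-p) * (1/pool_size + 1/coverage)` at each
  time point) are summed and divided by the summed standardisations. The
  per-SNP-ratio average is dominated by low-heterozygosity SNPs — abundant
  under a mean-0.14 spectrum — and overestimated `Ne` by nearly 20% in
  parameter-recovery runs; the ratio-of-sums weights SNPs by information
  content.
* **Linear inversion** `Ne = t / (2 * F_c)`. At `t = 59` generations the
  linearisation's downward bias in `F` and the heterozygosity loss from
  drift largely cancel; parameter recovery at a true `Ne` of 219 with 10^4
  SNPs and deep coverage lands within a few percent (223 +/- 3.5 across
  runs), well inside the 10% band the package tests.

Drift acts per replicate, so the pipeline estimates `Ne` replicate by
replicate and averages; averaging frequencies across replicates first would
shrink the drift signal K-fold. SNPs fixed in both samples carry no signal
and are dropped; if the corrected variance is not positive the drift signal
is below the sampling noise and `Ne` is reported as unidentifiable rather
than as a number.

# Selection-coefficient likelihood

`estimate_s()` computes, for each value on a grid of selection coefficients,
the exact likelihood of the evolved read counts: the `(2Ne+1)`-state
Wright-Fisher-with-selection Markov chain is propagated from the starting
frequency (a point mass at the nearest frequency state) for the observed
number of generations, and the observed minor-read count is emitted
binomially from the final state distribution. At `Ne = 219` the chain has
439 states and the computation is exact and deterministic — no simulation
noise enters the estimate. Replicates are combined by summing
log-likelihoods; the 95% interval is the chi-square likelihood-ratio set;
ties at the maximum break toward the smaller `|s|`, so a flat trajectory
returns the grid point nearest zero. The default grid `[-0.2, 0.2]` in steps
of 0.001 resolves the two-decimal reporting used throughout; recovery
simulations at true `s` in {0, 0.03, 0.07} show absolute bias below 0.01.

The grid evaluation reuses one transition matrix per `s` and shares the
forward propagation among replicates with equal starting states, which makes
the 200-replicate recovery tests cheap.

# Haplotype blocks from correlated trajectories

SNPs riding the same selected haplotype rise together in every replicate.
Candidate SNPs must have depth at least 20 in every sample and a polarised
frequency rise of at least 0.2 in *all* replicates (`filter_candidates()`;
alleles are polarised to the variant rising on average). Candidates are then
clustered by single-linkage at a Pearson correlation threshold of 0.95
(`cluster_trajectories()`), i.e. connected components of the thresholded
correlation graph; singletons are discarded.

The correlation is computed between *polarised frequency vectors
concatenated across replicates and time points* (10 values for five
replicates and two time points), not between per-replicate rise vectors.
The distinction matters: block members share both the ancestral-to-evolved
contrast and the replicate-level drift realisation, so their frequency
vectors correlate above 0.95 in most draws at 80x coverage, while the rise
vectors (five values, signal only in the drift spread) have member
correlations around 0.78 under independent binomial noise — the 0.95
threshold would shatter every true block. Independently drifting SNPs
correlate above 0.95 in about 0.1% of pairs, so false joins stay rare; the
permutation test in the suite bounds false clustering of noise-only
trajectories at 5%.

Block spans are exported in BED convention (0-based half-open), converted
from the 1-based inclusive sync coordinates.

# The quantitative-trait simulator

The trait model makes the contribution of the two focal loci quantifiable.
All loci act additively on one phenotype; raw effects (defaults 0.07 and
0.06 for the focal loci, background loci sharing a total of 0.5) are
normalised to sum to one, so the mean phenotype `sum(e_hat * p)` lies in
`[0, 1]` and is invariant to rescaling all raw effects. With background loci
at the spectrum mean of 0.14 the initial mean phenotype is 0.18, and fixing
the two focal loci raises it to 0.32 — the package's two analytic anchors.

Fitness is a bounded Gaussian function of the phenotype,
`w(z) = 0.5 + 1.0 * exp(-(z - optimum)^2 / (2 * 0.2^2))` at the defaults.
Each generation, every locus receives its marginal genotype fitnesses by
integrating `w` over the population's phenotype distribution, approximated
as normal with the mean and variance implied by the current allele
frequencies under linkage equilibrium (the Gaussian-kernel integral has a
closed form). Allele frequencies update by the standard one-locus selection
equation and then drift binomially at `N = 219`. Loci are independent: no
linkage, mutation, or epistasis. A consequence worth knowing: once a
large-effect homozygote overshoots the optimum, that locus becomes
effectively overdominant and equilibrates at an intermediate frequency
instead of fixing.

The proportion of phenotypic change explained by the focal loci is
`sum(e_hat_focal * dp_focal) / sum(e_hat * dp)`, with `dp` the change of the
replicate-averaged frequencies from generation 1 (the "initial value",
absorbing the first round of random variation) to the final generation; it
is undefined (reported `NA`) when the total change is not positive.

**Detection and the experiment-consistency rule.** Whether a locus "would
have been detected" is judged by a CMH test on binomial pseudo-counts at the
experimental coverage against a cutoff calibrated the way the real scan's
cutoff was: `calibrate_detection_cutoff()` simulates a large drift-only SNP
set at the experimental design and returns the p-value whose exceedance
probability equals the scan's selection rule (100 retained out of 2,741,793
tested), about 2e-21 at the defaults. `run_qt_grid()` then flags a parameter
cell *consistent with the experiment* when the focal loci are detected in at
least half of the simulations while the background loci are not: a trait
architecture whose background loci sweep detectably would have produced
additional scan peaks that were not observed, so such cells are excluded
when summarising what the focal loci can explain. Over the default grid
(background counts 5–1000, optima 0.3–0.7, 50 simulations per cell) the
minimum mean proportion among consistent cells lands just under 0.5: few
large background loci either betray themselves in the scan or leave most of
the change to the focal pair.

# Clinal reanalysis

For low-coverage individual sequencing (~1.8x), `classify_genotype()` uses
every read: no reads is unknown, both alleles seen is heterozygous,
otherwise the majority allele is called homozygous (a configurable minimum
for the rarer allele, default one read, tolerates sequencing error).
Population allele frequencies weight heterozygotes by half and drop SNPs
genotyped in fewer than half the individuals of any population
(`clinal_frequency()`).

Pooled population pairs are compared by per-SNP heterozygosity-based F_ST
with finite-read (`C/(C-1)`) and finite-pool (`n/(n-1)`) corrections, clipped
at zero; monomorphic or low-coverage (<10x) sites are undefined
(`pool_fst()`). `top_outliers()` applies an inverse-ECDF quantile threshold
(default top 0.1%) with strict exceedance, so ties at the threshold are
excluded.

Clinality of a candidate SNP set is tested by resampling
(`jackknife_clinal_test()`): the observed mean polarised north-south
frequency difference of the candidates is compared with the same statistic
on 10,000 random same-size subsets of the surrounding region, with the
add-one empirical p-value `(1 + #{null >= obs}) / (1 + n_draws)`. This
resampled-mean construction is exchangeable by design — its p-values are
uniform under the null and the type-I error sits at the nominal level —
which is preferred here over a per-set t statistic whose distribution would
depend on the unknown dependence among SNPs.

# The synthetic-data generator

`generate_scan()` produces the package's ground-truth experiments: neutral
SNPs drift independently at `Ne = 219` for 59 generations from
Beta-distributed starting frequencies (shapes 0.5 and 7.192, rejected
outside (0.05, 0.95); the second shape was solved so the truncated mean is
0.14), and planted haplotype blocks follow one shared selected trajectory
per replicate with independent binomial read noise per member SNP — linkage
without recombination, which is the structure the correlation-based block
caller needs to see. Because a *diagnostic* block is by definition one whose
members were all observed to rise concordantly, the planted block is
ascertained: each replicate's trajectory and member counts are redrawn until
every member shows an observed rise of at least 0.2 (`planted_block()`,
disable with `min_rise = NULL`). Without this conditioning roughly one run
in six has a replicate whose selected haplotype simply fails to rise 0.2 at
`Ne = 219` — a legitimate evolutionary outcome, but not the situation the
block caller is meant to be tested on.

What the generator deliberately does *not* emulate: recombination and
partially linked neutral hitchhikers, coverage heterogeneity along the
genome beyond Poisson, mapper artefacts, and correlated sampling noise
between nearby SNPs covered by the same reads. Passing recovery tests on
this generator therefore demonstrates the statistical machinery, not
robustness to alignment artefacts in real data.

`generate_cline()` draws Hardy-Weinberg genotypes along a latitudinal
frequency gradient and emits per-individual reads at a configurable depth
(default 1.8x), providing truth tables for the genotype-classification and
jackknife power tests.

# Numerical choices and problem sizes

* s-grids: `[-0.2, 0.2]` step 0.001 by default; recovery tests use step
  0.002 and worked examples `[0, 0.12]` step 0.001. Argmax ties break toward
  smaller `|s|`.
* The exact transition matrix is limited to about 1000 diploids (2001
  states); beyond that the method errors and suggests coarser tools.
* Quantile thresholds (`top_outliers()`, `calibrate_detection_cutoff()`) use
  the inverse-ECDF (type 1) definition, so reported thresholds are attained
  data values.
* Monte-Carlo sizes in the test-suite and acceptance computations are the
  package's own choices balancing stability against runtime: 10^4-SNP
  uniformity and Ne-recovery designs, 2x10^5-SNP null sets for the detection
  cutoff (the target quantile is 3.6e-5), 50 simulations per grid cell, 200
  trajectories per recovery point, 500 null trials for the jackknife
  type-I check.
* All simulators accept integer seeds and are bit-reproducible given one;
  the pipeline derives per-stage seeds deterministically from its master
  seed so stages can be re-run in isolation.

# Known limitations

* The temporal `Ne` correction is a two-stage sampling approximation, not a
  full likelihood; it is validated by parameter recovery at the design it
  targets (deep coverage, many SNPs, `t ~ 60`), and its small positive bias
  (a few percent) is visible in those runs.
* `estimate_s()` conditions on the observed starting frequency instead of
  modelling start-point sampling noise; at the deep coverages used for the
  focal haplotypes this is negligible.
* The quantitative-trait model is frequency-based (selection acts through
  marginal genotype fitnesses under a normal phenotype approximation); very
  few loci of very large effect push that approximation hardest, which is
  also where its qualitative behaviour (overshoot, equilibration) matters
  most.
* With only two time points, block calling cannot separate a selected
  haplotype from a tightly linked pair of independently selected variants;
  more time points would.
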