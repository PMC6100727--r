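# thermoevolve

Analysis toolkit for replicated **evolve-and-resequence (E&R)** experiments
with pooled sequencing, built around the question: when a population adapts
rapidly to a new thermal environment, how much of the response is carried by
a few large-effect loci segregating at intermediate frequency?

The package is aimed at population geneticists running (or simulating)
E&R designs of the classic Drosophila type — a handful of replicate cages,
tens of non-overlapping generations, ancestral and evolved pools sequenced
to moderate depth — and provides every computational stage on synthetic
data:

* **Wright-Fisher substrate** — forward simulation with additive selection
  (`1 : 1+s/2 : 1+s`), binomial drift at diploid size `Ne`, and Pool-Seq
  read sampling; PoPoolation2 `sync` format I/O.
* **Selection scan** — the Cochran-Mantel-Haenszel (CMH) test across
  replicate strata,
  `X^2 = (Σ_k (a_k − E[a_k]))^2 / Σ_k Var(a_k)` with hypergeometric moments
  and no continuity correction, plus the piece that makes it usable for E&R:
  an empirical false-positive rate calibrated by drift-only simulations
  matched to the observed starting-frequency spectrum (drift violates the
  CMH null, so chi-square p-values alone mean little). Conservative
  multi-mapper merging and ancestral read splitting are included.
* **Inference** — temporal effective population size under two-stage
  Pool-Seq sampling (plan I; `Ne = t / (2 F_c)` with read- and pool-size
  corrections), and maximum-likelihood selection coefficients from the exact
  `(2Ne+1)`-state Wright-Fisher Markov chain with binomial read emission.
* **Haplotype blocks** — reconstruction of selected haplotypes as
  single-linkage clusters of SNPs whose polarised frequency vectors
  (replicates × time points) correlate at ≥ 0.95, after conjunctive
  coverage (≥ 20) and rise (≥ 0.2 in every replicate) filters.
* **Quantitative-trait simulator** — all loci additive on one phenotype,
  bounded Gaussian fitness
  `w(z) = 0.5 + exp(−(z − optimum)^2 / (2·0.2^2))`, drift at `N = 219`;
  quantifies the share of phenotypic change explained by two focal
  large-effect loci across architectures (5–1000 background loci, optima
  0.3–0.7) and whether each locus would pass a drift-calibrated CMH cutoff.
* **Clinal tests** — low-coverage genotype classification, pooled per-SNP
  F_ST with finite-read and finite-pool corrections, top-quantile outliers,
  and a jackknife resampling test for candidate-SNP clinality.
* **Synthetic data & pipeline** — generators for scans with planted
  selected blocks and clinal panels with planted gradients (ground truth
  included), and `run_pipeline()` to chain everything with one master seed
  and a JSON manifest.

## Worked example

Simulate a 2,000-SNP experiment with one planted 28-SNP selected block
(starting frequency 0.44, `s = 0.07`, five replicates, 59 generations at
`Ne = 219`, 80× coverage), scan it, calibrate the false-positive rate, call
the block, and estimate its selection coefficient:

```r
library(thermoevolve)

scen <- scan_scenario(n_snps = 2000, ne = 219, generations = 59,
                      coverage = 80,
                      blocks = list(planted_block(28, p0 = 0.44, s = 0.07)))
sim <- generate_scan(scen, seed = 42)

scan   <- cmh_scan(sim$ancestral, sim$evolved)
cutoff <- top_k_cutoff(scan$p_value, 30)
cal    <- calibrate_fpr(scan$p_value, scan$anc_freq, ne = 219,
                        generations = 59, coverage = 80, n_runs = 5,
                        thresholds = cutoff, seed = 43)
cat(sprintf("tested %d SNPs; top-30 cutoff p = %.3g; FPR at cutoff = %.3f\n",
            nrow(scan), cutoff, cal$fpr))
#> tested 793 SNPs; top-30 cutoff p = 1.3e-12; FPR at cutoff = 0.053

blocks <- cluster_trajectories(
  filter_candidates(er_dataset(sim$ancestral, sim$evolved)))
blocks_as_table(blocks)
#>   chrom start    end n_snps mean_start_freq mean_rise
#> 1    2R 98600 101300     28       0.4342572  0.416152

b <- blocks[[1]]
traj <- trajectory(rbind(c(b$mean_start_freq,
                           b$mean_start_freq + mean(b$mean_rise))),
                   coverages = rbind(c(400, 80)), generations = c(0, 59))
estimate_s(traj, ne = 219, s_grid = seq(0, 0.12, by = 0.001))
#> s_hat = 0.0720  (95% LR CI 0.0120 .. 0.1200)
```

Reading the output: of 2,000 simulated sites, 793 pass the Pool-Seq
SNP-calling filter (coverage 5–500 and the minor allele seen in every
sample). At the p-value cutoff retaining the 30 most significant SNPs, the
drift-simulation calibration puts the false-positive rate at about 5% —
drift alone would have delivered ~1.6 of those 30. The block caller recovers
all 28 planted SNPs as one haplotype block (mean starting frequency 0.434,
mean rise 0.416 across replicates), and the exact Wright-Fisher likelihood
dates that rise at `s ≈ 0.07` per generation.

The full pipeline, with per-stage seeds and an output manifest:

```r
run_pipeline(list(seed = 1, out_dir = "demo_run"))
```

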