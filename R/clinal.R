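# Clinal reanalysis toolkit: low-coverage genotype classification, pooled
# F_ST with pool-size correction, outlier selection, and the jackknife
# resampling test for candidate-SNP clinality.

#' Classify a low-coverage individual genotype
#'
#' With very low depth (the clinal panels average ~1.8x), every read is used:
#' no reads means unknown, reads from only one allele mean homozygous for it,
#' and reads from both alleles mean heterozygous. To tolerate sequencing
#' error, a het call can be required to show at least `min_alt_reads` reads
#' of each allele (default 1, i.e. any second-allele read calls a het);
#' below that threshold the majority allele is called homozygous and exact
#' ties stay unknown.
#'
#' @param ref_reads,alt_reads Integer read counts (vectorised).
#' @param min_alt_reads Minimum reads of the rarer allele to call both
#'   alleles present.
#' @return Factor with levels `hom_ref`, `het`, `hom_alt`, `unknown`.
#' @export
classify_genotype <- function(ref_reads, alt_reads, min_alt_reads = 1L) {
  n <- max(length(ref_reads), length(alt_reads))
  ref_reads <- rep_len(ref_reads, n); alt_reads <- rep_len(alt_reads, n)
  out <- rep("unknown", n)
  het <- ref_reads >= min_alt_reads & alt_reads >= min_alt_reads &
    ref_reads > 0 & alt_reads > 0
  out[het] <- "het"
  # below the het threshold the rarer allele is treated as error: majority call
  out[!het & ref_reads > alt_reads] <- "hom_ref"
  out[!het & alt_reads > ref_reads] <- "hom_alt"
  factor(out, levels = c("hom_ref", "het", "hom_alt", "unknown"))
}

#' Clinal panel of individual genotypes
#'
#' @param genotypes List (one element per population, ordered along the
#'   cline, e.g. south to north) of genotype-class matrices
#'   `[snp x individual]` with entries from
#'   `hom_ref`/`het`/`hom_alt`/`unknown`.
#' @param populations Population labels.
#' @param snp_ids Optional SNP identifiers.
#' @return A `clinal_panel` object.
#' @export
clinal_panel <- function(genotypes, populations = names(genotypes),
                         snp_ids = NULL) {
  if (length(genotypes) < 2) stop("need at least two populations")
  n <- nrow(genotypes[[1]])
  stopifnot(all(vapply(genotypes, nrow, 0L) == n))
  if (is.null(populations)) populations <- paste0("pop", seq_along(genotypes))
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(n))
  structure(list(genotypes = genotypes, populations = populations,
                 snp_ids = snp_ids), class = "clinal_panel")
}

#' Per-population allele frequencies from genotype classes
#'
#' The alternate-allele frequency of a SNP in a population is
#' `(2 * hom_alt + het) / (2 * called)`. SNPs genotyped in fewer than
#' `min_called_fraction` of the individuals of any population are dropped.
#'
#' @param panel A [clinal_panel].
#' @param min_called_fraction Minimum fraction of individuals with a called
#'   genotype, required in every population (default 0.5).
#' @return Matrix `[snp x population]` of frequencies, retained SNPs only
#'   (row names are the SNP ids).
#' @export
clinal_frequency <- function(panel, min_called_fraction = 0.5) {
  stopifnot(inherits(panel, "clinal_panel"))
  np <- length(panel$genotypes)
  n <- nrow(panel$genotypes[[1]])
  freq <- called_frac <- matrix(NA_real_, n, np,
                                dimnames = list(panel$snp_ids,
                                                panel$populations))
  for (j in seq_len(np)) {
    g <- panel$genotypes[[j]]
    called <- g != "unknown"
    nc <- rowSums(called)
    called_frac[, j] <- if (ncol(g) > 0) nc / ncol(g) else 0
    freq[, j] <- (2 * rowSums(g == "hom_alt") + rowSums(g == "het")) / (2 * nc)
  }
  keep <- rowSums(called_frac < min_called_fraction) == 0
  freq[keep, , drop = FALSE]
}

#' Pairwise pooled F_ST with pool-size correction
#'
#' Heterozygosity-based per-SNP F_ST between two pools,
#' `(pi_total - pi_within) / pi_total`, with each heterozygosity corrected
#' for the finite number of reads and the finite number of chromosomes in
#' the pool (factors `C/(C-1)` and `n/(n-1)`). Negative values are clipped
#' to zero. Symmetric in its arguments and invariant to allele-label swaps.
#'
#' @param minor1,coverage1 Minor-allele reads and depth of pool 1
#'   (vectorised over SNPs).
#' @param minor2,coverage2 Same for pool 2.
#' @param pool_size1,pool_size2 Chromosomes in each pool.
#' @param min_coverage Minimum depth required in both pools (default 10);
#'   SNPs below it yield `NA`.
#' @return Per-SNP F_ST, `NA` where undefined (monomorphic pair or low
#'   coverage).
#' @export
pool_fst <- function(minor1, coverage1, minor2, coverage2,
                     pool_size1, pool_size2, min_coverage = 10) {
  p1 <- minor1 / coverage1
  p2 <- minor2 / coverage2
  het <- function(p, cov, n) 2 * p * (1 - p) * (cov / (cov - 1)) * (n / (n - 1))
  pi_w <- (het(p1, coverage1, pool_size1) + het(p2, coverage2, pool_size2)) / 2
  pt <- (minor1 + minor2) / (coverage1 + coverage2)
  pi_t <- het(pt, coverage1 + coverage2, pool_size1 + pool_size2)
  fst <- pmax((pi_t - pi_w) / pi_t, 0)
  fst[pt == 0 | pt == 1] <- NA_real_
  fst[coverage1 < min_coverage | coverage2 < min_coverage] <- NA_real_
  fst
}

#' Top-quantile outlier selection
#'
#' Returns the indices of values strictly above the empirical quantile
#' (inverse-ECDF definition), so a vector of `n` values with default
#' `quantile = 0.999` yields the top 0.1% of SNPs. Ties with the threshold
#' are excluded (strict `>`).
#'
#' @param values Per-SNP statistic (e.g. F_ST); `NA`s are ignored.
#' @param quantile Quantile defining the threshold (default 0.999).
#' @return List with `index` (positions in `values`) and `threshold`.
#' @export
top_outliers <- function(values, quantile = 0.999) {
  th <- as.numeric(stats::quantile(values, quantile, type = 1, na.rm = TRUE))
  list(index = which(!is.na(values) & values > th), threshold = th)
}

#' Jackknife resampling test for candidate-SNP clinality
#'
#' Tests whether candidate SNPs show a stronger polarised north-south
#' frequency difference than random SNP sets of the same size drawn from the
#' surrounding region. The observed statistic is the mean difference over
#' the candidates; the null distribution is the same statistic on
#' `n_draws` random subsets (without replacement) of the region's SNPs; the
#' empirical p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (1 + n_draws)`.
#'
#' @param freq_diff Named vector of per-SNP polarised frequency differences
#'   (e.g. selected-allele frequency in the southern minus the northern
#'   population) for every SNP of the region.
#' @param candidates Names (or integer indices) of the candidate SNPs; must
#'   all occur in `freq_diff`.
#' @param n_draws Number of random sets (default 10000).
#' @param seed Optional integer seed.
#' @return A `jackknife_result` list: `observed`, `null` (the resampled
#'   statistics) and `p_value`.
#' @export
jackknife_clinal_test <- function(freq_diff, candidates, n_draws = 10000L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(candidates)) {
    idx <- match(candidates, names(freq_diff))
    if (anyNA(idx)) stop("candidate SNPs missing from the region: ",
                         paste(candidates[is.na(idx)], collapse = ", "))
  } else {
    idx <- candidates
    if (any(idx < 1 | idx > length(freq_diff)))
      stop("candidate indices outside the region")
  }
  k <- length(idx)
  observed <- mean(freq_diff[idx])
  null <- vapply(seq_len(n_draws), function(i)
    mean(freq_diff[sample.int(length(freq_diff), k)]), 0)
  p <- (1 + sum(null >= observed)) / (1 + n_draws)
  structure(list(observed = observed, null = null, p_value = p,
                 n_draws = n_draws), class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("jackknife test: observed %.4f, p = %.4g (%d draws)\n",
              x$observed, x$p_value, x$n_draws))
  invisible(x)
}
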