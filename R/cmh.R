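# Replicated Cochran-Mantel-Haenszel selection scan, conservative
# multi-mapper merging and simulation-based false-positive calibration.

# internal vectorised CMH core: all arguments are [snp x K] matrices of
# counts (a, b = ancestral minor/major; c, d = evolved minor/major).
# Zero-margin strata contribute nothing and are dropped per SNP.
cmh_core <- function(a, b, c_, d) {
  n1 <- a + b; n2 <- c_ + d; m1 <- a + c_; m2 <- b + d
  tt <- n1 + n2
  ok <- n1 > 0 & n2 > 0 & m1 > 0 & m2 > 0
  ea <- n1 * m1 / tt
  va <- n1 * n2 * m1 * m2 / (tt^2 * (tt - 1))
  ea[!ok] <- 0; va[!ok] <- 0; a0 <- a; a0[!ok] <- 0
  num <- rowSums(a0 - ea)^2
  den <- rowSums(va)
  stat <- ifelse(den > 0, num / den, NA_real_)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       n_strata = rowSums(ok))
}

#' Cochran-Mantel-Haenszel test across replicates
#'
#' Tests for concordant allele-frequency change between ancestral and evolved
#' samples across K replicate strata. Each stratum is the 2x2 table of
#' minor/major read counts in the ancestral versus the evolved sample. The
#' statistic is `(sum_k (a_k - E[a_k]))^2 / sum_k Var(a_k)` with
#' hypergeometric mean and variance per stratum and no continuity correction
#' (counts are large in Pool-Seq); the p-value comes from the chi-square
#' distribution with one degree of freedom.
#'
#' Strata with a zero margin carry no information and are dropped with a
#' warning; if every stratum of a SNP is dropped the result is `NA` (an error
#' when a single SNP was supplied).
#'
#' @param anc_minor,anc_major Ancestral minor/major read counts: vectors of
#'   length K (one SNP) or `[snp x K]` matrices.
#' @param evo_minor,evo_major Evolved counts, same shape.
#' @return A data.frame of class `cmh_result` with columns `statistic`,
#'   `p_value` and `n_strata`.
#' @export
cmh_test <- function(anc_minor, anc_major, evo_minor, evo_major) {
  single <- is.null(dim(anc_minor))
  a <- rbind(anc_minor); b <- rbind(anc_major)
  c_ <- rbind(evo_minor); d <- rbind(evo_major)
  if (single) {
    a <- matrix(anc_minor, 1); b <- matrix(anc_major, 1)
    c_ <- matrix(evo_minor, 1); d <- matrix(evo_major, 1)
  }
  if (any(a < 0 | b < 0 | c_ < 0 | d < 0)) stop("counts must be non-negative")
  res <- cmh_core(a, b, c_, d)
  k <- ncol(a)
  if (any(res$n_strata < k))
    warning(sum(res$n_strata < k), " SNP(s) had zero-margin strata dropped")
  if (single && res$n_strata[1] == 0)
    stop("all strata have a zero margin; CMH statistic undefined")
  structure(data.frame(statistic = res$statistic, p_value = res$p_value,
                       n_strata = res$n_strata),
            class = c("cmh_result", "data.frame"))
}

#' Conservative merge across mapper tracks
#'
#' When the same SNP set has been tested on several alignment tracks (e.g.
#' different read mappers), retains for every SNP the track with the largest
#' (least significant) p-value. This guards against mapper-specific artefacts
#' at the cost of power.
#'
#' @param results A non-empty list of `cmh_result` data.frames over the same
#'   SNPs in the same order.
#' @return A single `cmh_result` with, per SNP, the least significant track.
#' @export
conservative_merge <- function(results) {
  if (!is.list(results) || length(results) == 0)
    stop("need at least one result track")
  if (length(results) == 1L) return(results[[1]])
  n <- nrow(results[[1]])
  if (!all(vapply(results, nrow, 0L) == n))
    stop("tracks cover different SNP sets")
  pmat <- vapply(results, function(r) r$p_value, numeric(n))
  pmat <- rbind(pmat)
  pick <- apply(pmat, 1, which.max)
  out <- results[[1]]
  for (i in seq_len(n)) out[i, ] <- results[[pick[i]]][i, ]
  out
}

#' Pool-Seq SNP-calling filter
#'
#' Retains SNPs whose per-sample coverage lies within `[min_coverage,
#' max_coverage]` in every sample and whose minor allele is supported by at
#' least `min_minor_reads` reads in every sample.
#'
#' @param counts Output of [allele_counts()] (or a list with
#'   `minor_counts` and `coverage` matrices).
#' @param min_coverage,max_coverage Per-sample depth bounds (defaults 5, 500).
#' @param min_minor_reads Minimum minor-allele reads per sample (default 1).
#' @return Logical vector marking retained SNPs.
#' @export
snp_filter <- function(counts, min_coverage = 5, max_coverage = 500,
                       min_minor_reads = 1) {
  cov_ok <- rowSums(counts$coverage < min_coverage |
                    counts$coverage > max_coverage) == 0
  minor_ok <- rowSums(counts$minor_counts < min_minor_reads) == 0
  cov_ok & minor_ok
}

#' Split pooled ancestral reads into pseudo-replicates
#'
#' The study design pools all ancestral reads and splits them at random into
#' K artificial samples so that the ancestral side matches the number of
#' evolved replicates. Reads are partitioned multinomially with equal
#' probabilities, separately for the two alleles.
#'
#' @param minor,major Integer vectors of pooled minor/major read counts per
#'   SNP.
#' @param k Number of pseudo-replicates.
#' @param seed Optional integer seed.
#' @return List with `minor` and `major` count matrices `[snp x k]`.
#' @export
split_ancestral <- function(minor, major, k, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  split1 <- function(x) t(vapply(x, function(m)
    as.integer(rmultinom(1, m, rep(1 / k, k))), integer(k)))
  list(minor = split1(minor), major = split1(major))
}

#' Simulation-based false-positive-rate calibration
#'
#' Simulates `n_runs` neutral SNP sets matching the empirical starting
#' frequency distribution and SNP count, evolves them by pure drift at `ne`
#' for `generations`, adds binomial Pool-Seq noise at the supplied mean
#' coverage (Poisson-varying per sample), runs the same CMH test, and reports
#' for each p-value threshold the empirical false positive rate
#' `FPR(theta) = mean_runs #\{neutral p <= theta\} / #\{empirical p <= theta\}`.
#' Thresholds with no empirical discovery have an undefined FPR, reported as
#' `NA` rather than zero.
#'
#' @param empirical_p Vector of empirical CMH p-values.
#' @param p0 Starting frequencies to resample for the neutral sets (typically
#'   the ancestral frequencies of the tested SNPs).
#' @param ne Effective population size for the neutral drift.
#' @param generations Generations of drift.
#' @param coverage Mean read depth of the Pool-Seq noise.
#' @param n_replicates Number of replicate strata (default 5).
#' @param n_runs Number of independent neutral runs (default 5).
#' @param thresholds Descending p-value cutoffs; default is a log-spaced grid
#'   spanning the empirical p-values.
#' @param seed Optional integer seed.
#' @return A data.frame of class `fpr_calibration` with columns `threshold`,
#'   `fpr`, `n_neutral` (mean count of neutral passes) and `n_empirical`.
#' @export
calibrate_fpr <- function(empirical_p, p0, ne, generations, coverage,
                          n_replicates = 5L, n_runs = 5L, thresholds = NULL,
                          seed = NULL) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (length(p0) == 0) stop("p0 distribution is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- length(empirical_p)
  if (is.null(thresholds)) {
    lo <- max(min(empirical_p), 1e-300)
    thresholds <- sort(10^seq(log10(lo), 0, length.out = 25), decreasing = TRUE)
  }
  null_counts <- matrix(0, n_runs, length(thresholds))
  for (r in seq_len(n_runs)) {
    ps <- sample(p0, n, replace = TRUE)
    pend <- vapply(seq_len(n_replicates), function(i)
      simulate_drift(ps, ne, generations), numeric(n))
    cov_a <- matrix(pmax(rpois(n * n_replicates, coverage), 1), n)
    cov_e <- matrix(pmax(rpois(n * n_replicates, coverage), 1), n)
    a <- matrix(rbinom(n * n_replicates, cov_a, ps), n)
    c_ <- matrix(rbinom(n * n_replicates, cov_e, pend), n)
    pv <- cmh_core(a, cov_a - a, c_, cov_e - c_)$p_value
    null_counts[r, ] <- vapply(thresholds, function(th)
      sum(pv <= th, na.rm = TRUE), 0)
  }
  emp <- vapply(thresholds, function(th) sum(empirical_p <= th), 0)
  fpr <- ifelse(emp > 0, colMeans(null_counts) / emp, NA_real_)
  structure(data.frame(threshold = thresholds, fpr = fpr,
                       n_neutral = colMeans(null_counts), n_empirical = emp),
            class = c("fpr_calibration", "data.frame"))
}

#' P-value cutoff retaining the top k SNPs
#'
#' @param p Vector of p-values.
#' @param k Number of SNPs to retain.
#' @return The k-th smallest p-value.
#' @export
top_k_cutoff <- function(p, k = 100L) {
  stopifnot(k >= 1, k <= length(p))
  sort(p, partial = k)[k]
}

#' Run a CMH scan from sync tables
#'
#' Convenience wrapper: biallelic reduction of ancestral and evolved sync
#' tables (replicate i of the ancestral table is paired with replicate i of
#' the evolved table), SNP-calling filter, CMH test.
#'
#' @param anc,evo [sync_table]s with the same SNPs and equally many samples.
#' @param min_coverage,max_coverage,min_minor_reads Passed to [snp_filter()].
#' @return A data.frame with `chrom`, `pos`, `statistic`, `p_value`,
#'   `n_strata` for the retained SNPs, plus ancestral/evolved mean minor
#'   frequencies.
#' @export
cmh_scan <- function(anc, evo, min_coverage = 5, max_coverage = 500,
                     min_minor_reads = 1) {
  stopifnot(n_snps(anc) == n_snps(evo), n_samples(anc) == n_samples(evo))
  ca <- allele_counts(anc)
  ce <- allele_counts(evo)
  both <- list(minor_counts = cbind(ca$minor_counts, ce$minor_counts),
               coverage = cbind(ca$coverage, ce$coverage))
  keep <- snp_filter(both, min_coverage, max_coverage, min_minor_reads)
  res <- cmh_test(ca$minor_counts[keep, , drop = FALSE],
                  ca$major_counts[keep, , drop = FALSE],
                  ce$minor_counts[keep, , drop = FALSE],
                  ce$major_counts[keep, , drop = FALSE])
  data.frame(chrom = anc$chrom[keep], pos = anc$pos[keep],
             statistic = res$statistic, p_value = res$p_value,
             n_strata = res$n_strata,
             anc_freq = rowMeans(ca$freq[keep, , drop = FALSE]),
             evo_freq = rowMeans(ce$freq[keep, , drop = FALSE]))
}
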