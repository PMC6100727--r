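# Temporal effective-population-size estimation under two-stage Pool-Seq
# sampling, and maximum-likelihood selection-coefficient inference via the
# exact Wright-Fisher Markov chain.

#' Temporal (plan I) effective population size from Pool-Seq data
#'
#' Standardised temporal variance estimator for pooled sequencing in which the
#' sequenced individuals are part of the breeding population (plan I). For
#' each SNP the squared frequency change `(p_start - p_end)^2` is standardised
#' by `z (1 - z)` with `z` the mean of the two frequencies; squared changes
#' and standardisations are combined as a ratio of sums (which weights SNPs by
#' their information content), after subtracting per-SNP two-stage sampling
#' variance `p(1-p) * (1/pool_size + 1/coverage)` at each time point. The
#' estimate is `ne = t / (2 * F_c)`.
#'
#' @param p_start,p_end Observed allele frequencies at the two time points.
#' @param coverage_start,coverage_end Read depths (scalar or per SNP).
#' @param pool_size Chromosomes sampled into each pool (scalar or per SNP).
#' @param generations Generations separating the samples.
#' @return A list with `ne`, the corrected variance `f_c` and `n_snps` used.
#'   SNPs fixed for the same allele in both samples carry no information and
#'   are dropped.
#' @export
estimate_ne <- function(p_start, p_end, coverage_start, coverage_end,
                        pool_size, generations) {
  stopifnot(length(p_start) == length(p_end), generations >= 1, all(pool_size >= 1))
  z <- (p_start + p_end) / 2
  keep <- z > 0 & z < 1
  if (!any(keep)) stop("no polymorphic SNPs between the two samples")
  x <- p_start[keep]; y <- p_end[keep]; z <- z[keep]
  cs <- rep(coverage_start, length.out = length(p_start))[keep]
  ce <- rep(coverage_end, length.out = length(p_start))[keep]
  ps <- rep(pool_size, length.out = length(p_start))[keep]
  corr_s <- 1 / ps + 1 / cs
  corr_e <- 1 / ps + 1 / ce
  f_c <- sum((x - y)^2 - corr_s * x * (1 - x) - corr_e * y * (1 - y)) /
    sum(z * (1 - z))
  if (f_c <= 0)
    stop("drift signal below sampling noise; ne unidentifiable (F_c <= 0)")
  list(ne = generations / (2 * f_c), f_c = f_c, n_snps = sum(keep))
}

# internal: log-likelihood curves over an s grid for a set of two-time-point
# observations sharing ne. Start states are treated as known (point mass at
# the nearest frequency state); evolved counts are emitted binomially.
# starts: vector of start frequencies; ks, covs: evolved minor counts and
# depths; dt: generations. Returns matrix [obs x grid].
wf_loglik_grid <- function(starts, ks, covs, dt, ne, s_grid) {
  n <- round(2 * ne)
  states <- (0:n) / n
  i0 <- round(starts * n) + 1L
  groups <- split(seq_along(starts), i0)
  # emission matrix P(k_i | state) is independent of s; build it once
  em <- vapply(seq_along(ks), function(i) dbinom(ks[i], covs[i], states),
               numeric(n + 1L))
  ll <- matrix(NA_real_, length(starts), length(s_grid))
  for (j in seq_along(s_grid)) {
    tm <- wf_transition_matrix(ne, s_grid[j])
    for (g in names(groups)) {
      idx <- groups[[g]]
      v <- numeric(n + 1L); v[as.integer(g)] <- 1
      for (gen in seq_len(dt)) v <- as.vector(v %*% tm)
      ll[idx, j] <- log(as.vector(v %*% em[, idx, drop = FALSE]))
    }
  }
  ll
}

#' Maximum-likelihood selection coefficient from a trajectory
#'
#' Computes the likelihood of the evolved allele counts by propagating the
#' exact `(2 * ne + 1)`-state Wright-Fisher Markov chain with additive
#' selection from the starting frequency and emitting the observed minor
#' read counts binomially, then maximises over a grid of selection
#' coefficients. Replicates are combined by summing log-likelihoods (or kept
#' separate with `combine = "per_replicate"`). Ties at the maximum are broken
#' toward the smaller `|s|`. The 95% confidence interval is the
#' likelihood-ratio interval (chi-square with one degree of freedom).
#'
#' @param traj A [trajectory] with at least two time points. If `coverages`
#'   is absent, a nominal depth of 100 reads is assumed for the emission.
#' @param ne Diploid effective size (<= ~1000; the method builds the exact
#'   transition matrix).
#' @param s_grid Grid of selection coefficients (default
#'   `seq(-0.2, 0.2, by = 0.001)`).
#' @param combine `"sum"` pools replicates into one estimate;
#'   `"per_replicate"` returns one estimate per replicate (no CI).
#' @return For `combine = "sum"` an `s_estimate` list with `s_hat`, `ci`,
#'   `s_grid` and `log_likelihood`; for `"per_replicate"` a numeric vector of
#'   per-replicate estimates.
#' @export
estimate_s <- function(traj, ne, s_grid = seq(-0.2, 0.2, by = 0.001),
                       combine = c("sum", "per_replicate")) {
  combine <- match.arg(combine)
  stopifnot(inherits(traj, "trajectory"))
  if (length(s_grid) == 0) stop("empty s grid")
  if (round(2 * ne) > 2000)
    stop("ne too large for the exact matrix method; coarsen or use a ",
         "normal approximation")
  f <- traj$frequencies
  if (ncol(f) < 2) stop("trajectory needs at least two time points")
  gens <- traj$generations
  cov <- traj$coverages
  if (is.null(cov)) cov <- matrix(100L, nrow(f), ncol(f))
  if (ncol(f) > 2) {
    # use first and last time point; intermediate points would require full
    # HMM filtering, unnecessary for the two-point designs targeted here
    f <- f[, c(1, ncol(f)), drop = FALSE]
    cov <- cov[, c(1, ncol(cov)), drop = FALSE]
    gens <- gens[c(1, length(gens))]
  }
  dt <- gens[2] - gens[1]
  if (dt < 1) stop("time points must span at least one generation")
  ks <- round(f[, 2] * cov[, 2])
  ll <- wf_loglik_grid(f[, 1], ks, cov[, 2], dt, ne, s_grid)
  argmax_small <- function(v) {
    cand <- which(v >= max(v) - 1e-12)
    cand[which.min(abs(s_grid[cand]))]
  }
  if (combine == "per_replicate")
    return(s_grid[apply(ll, 1, argmax_small)])
  tot <- colSums(ll)
  best <- argmax_small(tot)
  in_ci <- 2 * (tot[best] - tot) <= qchisq(0.95, 1)
  structure(list(s_hat = s_grid[best],
                 ci = range(s_grid[in_ci]),
                 s_grid = s_grid, log_likelihood = tot),
            class = "s_estimate")
}

#' @export
print.s_estimate <- function(x, ...) {
  cat(sprintf("s_hat = %.4f  (95%% LR CI %.4f .. %.4f)\n",
              x$s_hat, x$ci[1], x$ci[2]))
  invisible(x)
}
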