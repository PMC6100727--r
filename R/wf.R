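# Wright-Fisher forward machinery: deterministic selection update, binomial
# drift, exact transition matrices and Pool-Seq sampling noise.

#' Wright-Fisher simulation parameters
#'
#' Additive selection with genotype fitnesses 1 : 1 + s/2 : 1 + s
#' (dominance fixed at 0.5). `ne` is the diploid effective size, so drift acts
#' through binomial sampling of `2 * ne` gametes per generation.
#'
#' @param ne Diploid effective population size (>= 1).
#' @param s Selection coefficient of the favoured homozygote per generation.
#' @param generations Number of generations (>= 0).
#' @param p0 Initial frequency of the selected (minor) allele in `[0, 1]`.
#' @param h Dominance coefficient; only the additive value 0.5 is supported.
#' @return A `wf_params` list.
#' @export
wf_params <- function(ne, s = 0, generations = 0L, p0 = 0.5, h = 0.5) {
  if (!is.numeric(ne) || ne < 1) stop("ne must be >= 1")
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]")
  if (generations < 0) stop("generations must be >= 0")
  if (h != 0.5) stop("only additive selection (h = 0.5) is implemented")
  structure(list(ne = ne, s = s, h = h, generations = as.integer(generations),
                 p0 = p0), class = "wf_params")
}

#' Deterministic selection update
#'
#' Expected frequency after one generation of additive selection:
#' `p' = p * (p * (1 + s) + (1 - p) * (1 + s/2)) / (1 + s * p)`.
#' With `s = 0` this is the identity; 0 and 1 are absorbing.
#'
#' @param p Allele frequency (vectorised).
#' @param s Selection coefficient.
#' @return Updated frequency.
#' @export
wf_select <- function(p, s) {
  if (any(p < 0 | p > 1)) stop("frequency outside [0, 1]")
  p * (p * (1 + s) + (1 - p) * (1 + s / 2)) / (1 + s * p)
}

#' One stochastic Wright-Fisher generation
#'
#' Applies the deterministic selection update, then binomial sampling of
#' `2 * ne` gametes. Vectorised over loci.
#'
#' @param p Allele frequencies.
#' @param ne Diploid effective size.
#' @param s Selection coefficient (scalar or per-locus).
#' @return Sampled offspring frequencies on the grid `k / (2 * ne)`.
#' @export
wf_step <- function(p, ne, s = 0) {
  if (ne < 1) stop("ne must be >= 1")
  n <- round(2 * ne)
  rbinom(length(p), n, wf_select(p, s)) / n
}

#' Exact Wright-Fisher transition matrix
#'
#' Row `i + 1` is the offspring distribution of a population currently at
#' frequency `i / (2 * ne)`: `Binomial(2 * ne, wf_select(i / (2 * ne), s))`.
#' Rows sum to one; states 0 and `2 * ne` are absorbing.
#'
#' @param ne Diploid effective size (kept modest; the matrix has
#'   `(2 * ne + 1)^2` entries).
#' @param s Selection coefficient.
#' @return A dense `(2 * ne + 1) x (2 * ne + 1)` matrix.
#' @export
wf_transition_matrix <- function(ne, s = 0) {
  n <- round(2 * ne)
  if (n > 5000) stop("ne too large for the exact matrix; use simulation")
  p <- wf_select((0:n) / n, s)
  t(vapply(p, function(pp) dbinom(0:n, n, pp), numeric(n + 1)))
}

#' Simulate replicate allele-frequency trajectories
#'
#' Independent replicate populations evolve from `params$p0` under selection
#' and drift. With a fixed seed the output is reproducible bit for bit.
#'
#' @param params A [wf_params] object.
#' @param n_replicates Number of independent replicates.
#' @param seed Optional integer seed.
#' @param coverage Optional read depth; when supplied, each recorded frequency
#'   is replaced by a Pool-Seq binomial read-sampled estimate at that depth
#'   and the trajectory carries the coverages.
#' @return A [trajectory] with one row per replicate and one column per
#'   recorded generation (0 .. generations).
#' @export
simulate_trajectory <- function(params, n_replicates = 1L, seed = NULL,
                                coverage = NULL) {
  stopifnot(inherits(params, "wf_params"), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  t <- params$generations
  freq <- matrix(NA_real_, n_replicates, t + 1L)
  freq[, 1] <- params$p0
  p <- rep(params$p0, length.out = n_replicates)
  for (g in seq_len(t)) {
    p <- wf_step(p, params$ne, params$s)
    freq[, g + 1L] <- p
  }
  cov <- NULL
  if (!is.null(coverage)) {
    cov <- matrix(rpois(length(freq), coverage), nrow(freq), ncol(freq))
    cov[cov < 1] <- 1L
    freq <- matrix(rbinom(length(freq), cov, freq), nrow(freq)) / cov
  }
  trajectory(freq, coverages = cov, generations = 0:t)
}

#' Vectorised drift endpoints for many loci
#'
#' Evolves a vector of starting frequencies through `generations` of
#' Wright-Fisher sampling (optional selection) and returns only the final
#' frequencies. This is the workhorse for genome-scale neutral simulations.
#'
#' @param p0 Starting frequencies (one per locus).
#' @param ne Diploid effective size.
#' @param generations Number of generations.
#' @param s Selection coefficient (scalar or per-locus).
#' @return Final frequencies.
#' @export
simulate_drift <- function(p0, ne, generations, s = 0) {
  p <- p0
  for (g in seq_len(generations)) p <- wf_step(p, ne, s)
  p
}

#' Pool-Seq read sampling
#'
#' Draws the minor-allele read count as `Binomial(coverage, true_freq)`,
#' the standard model of Pool-Seq sampling noise.
#'
#' @param true_freq True allele frequency (vectorised).
#' @param coverage Read depth (scalar or per-locus, >= 0).
#' @param seed Optional integer seed.
#' @return A data.frame with columns `major_count` and `minor_count`.
#' @export
pool_sample <- function(true_freq, coverage, seed = NULL) {
  if (any(true_freq < 0 | true_freq > 1)) stop("frequency outside [0, 1]")
  if (any(coverage < 0)) stop("coverage must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  k <- rbinom(max(length(true_freq), length(coverage)), coverage, true_freq)
  data.frame(major_count = as.integer(coverage - k), minor_count = as.integer(k))
}

#' Allele-frequency trajectory container
#'
#' @param frequencies Matrix `[replicate x time point]` of frequencies in
#'   `[0, 1]`.
#' @param coverages Optional matrix of read depths with matching dimensions.
#' @param generations Time-point labels (generation numbers).
#' @return A `trajectory` object.
#' @export
trajectory <- function(frequencies, coverages = NULL, generations = NULL) {
  frequencies <- rbind(frequencies)
  if (any(frequencies < 0 | frequencies > 1, na.rm = TRUE))
    stop("frequencies outside [0, 1]")
  if (is.null(generations)) generations <- seq_len(ncol(frequencies)) - 1L
  if (length(generations) != ncol(frequencies))
    stop("generations labels do not match time points")
  if (!is.null(coverages)) {
    coverages <- rbind(coverages)
    if (!all(dim(coverages) == dim(frequencies)))
      stop("dimensions of frequencies and coverages disagree")
  }
  structure(list(frequencies = frequencies, coverages = coverages,
                 generations = generations), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d replicate(s), generations %s\n",
              nrow(x$frequencies), paste(x$generations, collapse = ", ")))
  invisible(x)
}
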