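# Synthetic-data generators: replicated E&R pool counts with planted
# selected haplotype blocks, neutral scans for calibration, and clinal
# genotype panels with planted gradients.

#' Sample starting frequencies from the site-frequency spectrum
#'
#' Rejection-samples a Beta distribution restricted to `(lower, upper)`.
#' The default shapes (0.5, 7.192) were solved so that the truncated mean
#' equals 0.14, the mean starting frequency of the ancestral population.
#'
#' @param n Number of frequencies.
#' @param shape1,shape2 Beta shapes (defaults 0.5 and 7.192).
#' @param lower,upper Truncation bounds (defaults 0.05 and 0.95).
#' @param seed Optional integer seed.
#' @return Numeric vector in `(lower, upper)`.
#' @export
sfs_sample <- function(n, shape1 = 0.5, shape2 = 7.192,
                       lower = 0.05, upper = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rbeta(max(2L * (n - length(out)), 100L), shape1, shape2)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Planted haplotype block specification
#'
#' A selected haplotype block carrying `n_snps` linked SNPs at a shared
#' intermediate starting frequency. A diagnostic block is, by definition,
#' one whose member SNPs were all observed to rise concordantly in every
#' replicate; by default the generator reproduces that ascertainment by
#' rejection-sampling each replicate (trajectory plus read counts) until
#' every member SNP shows an observed rise of at least `min_rise`. Set
#' `min_rise = NULL` for unconditioned selected trajectories (e.g. for power
#' studies).
#'
#' @param n_snps SNPs on the block (default 28).
#' @param p0 Shared starting frequency (default 0.44).
#' @param s Selection coefficient (default 0.07).
#' @param min_rise Ascertainment condition on the observed per-replicate
#'   rise of every member SNP (default 0.2, the diagnostic-SNP filter
#'   threshold).
#' @return A `planted_block` list.
#' @export
planted_block <- function(n_snps = 28L, p0 = 0.44, s = 0.07, min_rise = 0.2) {
  stopifnot(n_snps >= 1, p0 > 0, p0 < 1)
  structure(list(n_snps = as.integer(n_snps), p0 = p0, s = s,
                 min_rise = min_rise), class = "planted_block")
}

#' Scan scenario specification
#'
#' Describes a synthetic replicated E&R experiment: a window of neutral SNPs
#' with starting frequencies from the site-frequency spectrum, optionally
#' with planted selected haplotype blocks. Linkage within a block is modelled
#' as a single shared selected-haplotype trajectory per replicate, with
#' independent Pool-Seq sampling noise per member SNP (no recombination).
#'
#' @param n_snps Total SNPs, planted ones included (default 10000).
#' @param ne Effective population size (default 219).
#' @param generations Generations of evolution (default 59).
#' @param n_replicates Replicates (default 5).
#' @param coverage Mean read depth; per-sample depths are Poisson
#'   (default 80).
#' @param blocks List of [planted_block()]s (default one 28-SNP block at
#'   starting frequency 0.44 with s = 0.07); use `list()` for a purely
#'   neutral scan.
#' @param block_positions Starting index of each block inside the window
#'   (default places blocks consecutively at the centre).
#' @param chrom Chromosome label (default `"2R"`).
#' @param sfs Function `function(n)` drawing neutral starting frequencies
#'   (default [sfs_sample()]).
#' @return A `scan_scenario` list.
#' @export
scan_scenario <- function(n_snps = 10000L, ne = 219, generations = 59L,
                          n_replicates = 5L, coverage = 80,
                          blocks = list(planted_block()),
                          block_positions = NULL, chrom = "2R",
                          sfs = sfs_sample) {
  n_planted <- sum(vapply(blocks, function(b) b$n_snps, 0L))
  stopifnot(n_snps >= n_planted)
  if (is.null(block_positions) && length(blocks) > 0) {
    start <- max(1L, (n_snps - n_planted) %/% 2L)
    block_positions <- integer(length(blocks))
    for (i in seq_along(blocks)) {
      block_positions[i] <- start
      start <- start + blocks[[i]]$n_snps
    }
  }
  structure(list(n_snps = as.integer(n_snps), ne = ne,
                 generations = as.integer(generations),
                 n_replicates = as.integer(n_replicates), coverage = coverage,
                 blocks = blocks, block_positions = block_positions,
                 chrom = chrom, sfs = sfs),
            class = "scan_scenario")
}

#' Generate a synthetic replicated E&R scan
#'
#' Neutral SNPs evolve by drift only; SNPs of a planted block follow one
#' shared selected trajectory per replicate (drift plus additive selection at
#' the block's `s`). All true frequencies are then read-sampled binomially at
#' Poisson-varying coverage into ancestral and evolved sync tables. The truth
#' table lists every planted SNP.
#'
#' @param scenario A [scan_scenario].
#' @param seed Optional integer seed; identical seeds give identical files.
#' @return List with `ancestral` and `evolved` [sync_table]s (one sample per
#'   replicate each), and `truth`: a data.frame of all SNPs with `pos`,
#'   `p0`, `selected`, `s`, `block`.
#' @export
generate_scan <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scan_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_snps
  k <- scenario$n_replicates
  p0 <- scenario$sfs(n)
  sel <- rep(FALSE, n); svec <- rep(0, n); block_id <- rep(NA_integer_, n)
  for (i in seq_along(scenario$blocks)) {
    b <- scenario$blocks[[i]]
    idx <- scenario$block_positions[i] + seq_len(b$n_snps) - 1L
    p0[idx] <- b$p0; sel[idx] <- TRUE; svec[idx] <- b$s; block_id[idx] <- i
  }
  # true end frequencies: independent drift for neutral SNPs, one shared
  # trajectory per (block, replicate) for planted SNPs
  pend <- matrix(NA_real_, n, k)
  neutral <- !sel
  for (r in seq_len(k)) {
    pend[neutral, r] <- simulate_drift(p0[neutral], scenario$ne,
                                       scenario$generations)
  }
  draw_counts <- function(freq_mat) {
    nn <- length(freq_mat)
    cov <- matrix(pmax(rpois(nn, scenario$coverage), 1), nrow(freq_mat))
    minor <- matrix(rbinom(nn, cov, freq_mat), nrow(freq_mat))
    list(minor = minor, cov = cov)
  }
  pend[!neutral, ] <- 0   # placeholder; overwritten by the block draws below
  anc <- draw_counts(matrix(p0, n, k))
  evo <- draw_counts(pend)
  # planted blocks: per replicate, draw the shared selected trajectory and
  # the block's read counts jointly; when ascertained, reject until every
  # member SNP shows an observed rise of at least min_rise in this replicate
  for (i in seq_along(scenario$blocks)) {
    b <- scenario$blocks[[i]]
    idx <- which(block_id == i)
    for (r in seq_len(k)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        ptraj <- simulate_drift(b$p0, scenario$ne, scenario$generations,
                                s = b$s)
        cov_a <- pmax(rpois(length(idx), scenario$coverage), 1)
        cov_e <- pmax(rpois(length(idx), scenario$coverage), 1)
        ka <- rbinom(length(idx), cov_a, b$p0)
        ke <- rbinom(length(idx), cov_e, ptraj)
        if (is.null(b$min_rise) ||
            all(ke / cov_e - ka / cov_a >= b$min_rise)) break
        if (tries >= 10000L)
          stop("block ascertainment condition not met in 10000 draws; ",
               "is the block's selection strong enough to be diagnostic?")
      }
      pend[idx, r] <- ptraj
      anc$cov[idx, r] <- cov_a; anc$minor[idx, r] <- ka
      evo$cov[idx, r] <- cov_e; evo$minor[idx, r] <- ke
    }
  }
  pos <- seq_len(n) * 100L   # evenly spaced positions along the window
  list(ancestral = sync_from_counts(scenario$chrom, pos, anc$minor, anc$cov),
       evolved = sync_from_counts(scenario$chrom, pos, evo$minor, evo$cov),
       truth = data.frame(chrom = scenario$chrom, pos = pos, p0 = p0,
                          selected = sel, s = svec, block = block_id))
}

#' Generate a clinal genotype panel with a planted gradient
#'
#' Simulates individual genotypes in populations ordered along a geographic
#' transect. Each SNP gets a base frequency from the site-frequency spectrum
#' and a linear latitudinal gradient of total span `gradient` (frequency at
#' the last population minus the first); genotypes are Hardy-Weinberg draws
#' and per-individual read counts are Poisson at `depth` with binomial
#' allele sampling (heterozygotes emit either allele with probability 1/2).
#'
#' @param n_pops Number of populations (>= 2, default 4).
#' @param n_individuals Individuals per population (default 20).
#' @param n_snps Number of SNPs (default 100).
#' @param gradient Frequency span across the cline; a vector gives per-SNP
#'   gradients (default 0.3).
#' @param depth Mean per-individual depth (default 1.8).
#' @param seed Optional integer seed.
#' @return List with `panel` (a [clinal_panel]), `truth` (matrix of true
#'   frequencies `[snp x population]`) and `reads` (per-population list of
#'   `ref`/`alt` count matrices).
#' @export
generate_cline <- function(n_pops = 4L, n_individuals = 20L, n_snps = 100L,
                           gradient = 0.3, depth = 1.8, seed = NULL) {
  stopifnot(n_pops >= 2)
  if (!is.null(seed)) set.seed(seed)
  base <- sfs_sample(n_snps)
  grad <- rep_len(gradient, n_snps)
  lat <- seq(0, 1, length.out = n_pops)
  truth <- vapply(lat, function(l) pmin(pmax(base + l * grad, 0), 1),
                  numeric(n_snps))
  genotypes <- vector("list", n_pops)
  reads <- vector("list", n_pops)
  for (j in seq_len(n_pops)) {
    dos <- matrix(rbinom(n_snps * n_individuals, 2, truth[, j]),
                  n_snps, n_individuals)
    cov <- matrix(rpois(n_snps * n_individuals, depth), n_snps, n_individuals)
    alt <- matrix(rbinom(length(dos), cov, dos / 2), n_snps, n_individuals)
    ref <- cov - alt
    cls <- matrix(as.character(classify_genotype(ref, alt)),
                  n_snps, n_individuals)
    genotypes[[j]] <- cls
    reads[[j]] <- list(ref = ref, alt = alt)
  }
  names(genotypes) <- paste0("pop", seq_len(n_pops))
  list(panel = clinal_panel(genotypes), truth = truth, reads = reads)
}
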