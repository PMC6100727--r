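# Reconstruction of selected haplotype blocks from SNPs whose frequency
# trajectories are correlated across replicates.

#' Block-calling parameters
#'
#' @param min_correlation Minimum pairwise Pearson correlation of rise
#'   vectors for two SNPs to be linked (default 0.95).
#' @param min_coverage Minimum read depth required in every sample
#'   (default 20).
#' @param min_rise Minimum polarised allele-frequency change required in
#'   every replicate (default 0.2).
#' @return A `block_params` list.
#' @export
block_params <- function(min_correlation = 0.95, min_coverage = 20,
                         min_rise = 0.2) {
  if (min_correlation <= 0 || min_correlation > 1)
    stop("min_correlation must lie in (0, 1]")
  if (min_rise <= 0 || min_rise >= 1) stop("min_rise must lie in (0, 1)")
  structure(list(min_correlation = min_correlation,
                 min_coverage = min_coverage, min_rise = min_rise),
            class = "block_params")
}

#' Pair ancestral and evolved sync tables into an E&R data set
#'
#' Replicate i of the ancestral table is paired with replicate i of the
#' evolved table; frequencies come from the joint biallelic reduction so both
#' time points refer to the same minor allele.
#'
#' @param anc,evo [sync_table]s with identical SNPs and equally many samples.
#' @return An `er_dataset` list with `chrom`, `pos`, frequency matrices
#'   `anc_freq`, `evo_freq` `[snp x replicate]` and the full coverage matrix.
#' @export
er_dataset <- function(anc, evo) {
  stopifnot(n_snps(anc) == n_snps(evo), n_samples(anc) == n_samples(evo))
  k <- n_samples(anc)
  cnt <- array(0L, c(n_snps(anc), 2L * k, 6L))
  cnt[, seq_len(k), ] <- anc$counts
  cnt[, k + seq_len(k), ] <- evo$counts
  merged <- sync_table(anc$chrom, anc$pos, anc$ref, cnt)
  cc <- allele_counts(merged)
  structure(list(chrom = anc$chrom, pos = anc$pos,
                 anc_freq = cc$freq[, seq_len(k), drop = FALSE],
                 evo_freq = cc$freq[, k + seq_len(k), drop = FALSE],
                 coverage = cc$coverage),
            class = "er_dataset")
}

#' Filter candidate SNPs for block reconstruction
#'
#' Applies the block-calling filters: depth at least `min_coverage` in every
#' sample and a polarised frequency change of at least `min_rise` in every
#' replicate. Alleles are polarised to the variant rising on average across
#' replicates before the conjunctive rise test.
#'
#' @param x An [er_dataset].
#' @param params A [block_params] object.
#' @return A `candidate_set` list: `chrom`, `pos`, `start_freq` (mean
#'   polarised ancestral frequency), the polarised `rise` matrix
#'   `[snp x replicate]`, and `traj`, the polarised frequencies concatenated
#'   across replicates and time points (ancestral then evolved), used for
#'   the correlation clustering.
#' @export
filter_candidates <- function(x, params = block_params()) {
  stopifnot(inherits(x, "er_dataset"))
  rise <- x$evo_freq - x$anc_freq
  pol <- ifelse(rowMeans(rise) >= 0, 1, -1)
  rise <- rise * pol
  flip <- pol < 0
  anc_pol <- x$anc_freq; anc_pol[flip, ] <- 1 - anc_pol[flip, ]
  evo_pol <- x$evo_freq; evo_pol[flip, ] <- 1 - evo_pol[flip, ]
  anc <- rowMeans(anc_pol)
  keep <- rowSums(x$coverage < params$min_coverage) == 0 &
    rowSums(rise < params$min_rise) == 0
  structure(list(chrom = x$chrom[keep], pos = x$pos[keep],
                 start_freq = anc[keep],
                 rise = rise[keep, , drop = FALSE],
                 traj = cbind(anc_pol, evo_pol)[keep, , drop = FALSE]),
            class = "candidate_set")
}

#' Cluster correlated trajectories into haplotype blocks
#'
#' Computes Pearson correlations between the polarised frequency vectors of
#' all candidate SNPs, concatenated across replicates and time points, and
#' joins SNPs into blocks by single-linkage at the correlation threshold
#' (connected components of the thresholded correlation graph). SNPs riding
#' the same selected haplotype share both the ancestral-to-evolved contrast
#' and the replicate-to-replicate drift realisation, so their vectors
#' correlate strongly, while independently drifting SNPs do not. Singletons
#' are discarded; SNPs with zero-variance vectors are skipped with a
#' warning.
#'
#' @param candidates A `candidate_set` from [filter_candidates()].
#' @param params A [block_params] object.
#' @return A list of `haplotype_block` objects, each with member `pos`,
#'   `mean_start_freq` and `mean_rise` per replicate. Also available as a
#'   table via [blocks_as_table()].
#' @export
cluster_trajectories <- function(candidates, params = block_params()) {
  stopifnot(inherits(candidates, "candidate_set"))
  n <- length(candidates$pos)
  if (n < 2) return(list())
  v <- apply(candidates$traj, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " SNP(s) with constant trajectories skipped")
  }
  use <- which(v > 0)
  if (length(use) < 2) return(list())
  cm <- cor(t(candidates$traj[use, , drop = FALSE]))
  adj <- cm >= params$min_correlation
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  blocks <- list()
  for (cid in unique(comp)) {
    idx <- use[comp == cid]
    if (length(idx) < 2) next
    blocks[[length(blocks) + 1L]] <- structure(
      list(chrom = candidates$chrom[idx][1], pos = candidates$pos[idx],
           mean_start_freq = mean(candidates$start_freq[idx]),
           mean_rise = colMeans(candidates$rise[idx, , drop = FALSE])),
      class = "haplotype_block")
  }
  # deterministic order: by leftmost member position
  blocks[order(vapply(blocks, function(b) min(b$pos), 0))]
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype block: %d SNPs, %s:%d-%d, start freq %.3f, mean rise %.3f\n",
              length(x$pos), x$chrom, min(x$pos), max(x$pos),
              x$mean_start_freq, mean(x$mean_rise)))
  invisible(x)
}

#' Tabulate haplotype blocks
#'
#' @param blocks List of blocks from [cluster_trajectories()].
#' @return Data.frame with one row per block: span, member count, mean
#'   starting frequency and mean rise.
#' @export
blocks_as_table <- function(blocks) {
  if (length(blocks) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      mean_start_freq = numeric(0), mean_rise = numeric(0)))
  data.frame(chrom = vapply(blocks, function(b) b$chrom, ""),
             start = vapply(blocks, function(b) min(b$pos), 0L),
             end = vapply(blocks, function(b) max(b$pos), 0L),
             n_snps = vapply(blocks, function(b) length(b$pos), 0L),
             mean_start_freq = vapply(blocks, function(b) b$mean_start_freq, 0),
             mean_rise = vapply(blocks, function(b) mean(b$mean_rise), 0))
}

#' Haplotype-block spans as BED intervals
#'
#' Converts 1-based inclusive sync coordinates to the 0-based half-open BED
#' convention.
#'
#' @param blocks List of blocks from [cluster_trajectories()].
#' @return Data.frame with `chrom`, `start` (0-based), `end` (exclusive).
#' @export
blocks_to_bed <- function(blocks) {
  tab <- blocks_as_table(blocks)
  data.frame(chrom = tab$chrom, start = tab$start - 1L, end = tab$end)
}
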