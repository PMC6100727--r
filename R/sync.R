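#' @importFrom data.table fread fwrite tstrsplit data.table :=
#' @importFrom stats rbinom rpois rbeta rmultinom pchisq qchisq quantile
#'   ks.test cor dbinom setNames
#' @importFrom utils head tail
NULL

SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

#' Construct a sync table
#'
#' A sync table holds per-SNP, per-population-sample allele read counts in the
#' PoPoolation2 convention: for every sample the six counts A:T:C:G:N:del.
#' It is the universal exchange object of the package: simulators write it,
#' scans and block callers read it.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref Character vector of reference nucleotides.
#' @param counts Integer array `[n_snp, n_sample, 6]`; the third dimension is
#'   ordered A, T, C, G, N, del.
#' @return An object of class `sync_table`.
#' @export
sync_table <- function(chrom, pos, ref, counts) {
  n <- length(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(ref) == n)
  if (n > 0) {
    if (is.matrix(counts)) counts <- array(counts, c(n, 1L, 6L))
    stopifnot(length(dim(counts)) == 3L, dim(counts)[1] == n, dim(counts)[3] == 6L)
    if (any(counts < 0)) stop("negative allele counts")
    bad <- tapply(pos, chrom, function(p) any(diff(p) <= 0))
    if (any(unlist(bad)))
      stop("positions must be strictly increasing within a chromosome")
  } else {
    counts <- array(integer(0), c(0L, if (missing(counts)) 0L else dim(counts)[2], 6L))
  }
  dimnames(counts)[[3]] <- SYNC_ALLELES
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts),
            class = "sync_table")
}

#' @export
print.sync_table <- function(x, ...) {
  cat(sprintf("sync_table: %d SNPs x %d samples\n", n_snps(x), n_samples(x)))
  if (n_snps(x) > 0) {
    cat(sprintf("  chromosomes: %s\n", paste(unique(x$chrom), collapse = ", ")))
    cat(sprintf("  positions: %d..%d\n", min(x$pos), max(x$pos)))
  }
  invisible(x)
}

#' Number of SNPs / samples in a sync table
#' @param x A `sync_table`.
#' @return Integer count.
#' @export
n_snps <- function(x) length(x$pos)

#' @rdname n_snps
#' @export
n_samples <- function(x) dim(x$counts)[2]

#' Read a PoPoolation2 sync file
#'
#' Parses the tab-separated sync dialect
#' `chrom<TAB>pos<TAB>ref<TAB>A:T:C:G:N:del ...`. Malformed rows (ragged
#' columns, count fields without six entries, non-numeric counts) raise an
#' error naming the offending line. An empty file yields an empty table.
#'
#' @param path Path to a sync file.
#' @return A [sync_table].
#' @export
read_sync <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(sync_table(character(0), integer(0), character(0),
                      array(integer(0), c(0L, 0L, 6L))))
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
              fill = TRUE)
  if (ncol(dt) < 4L) stop("sync file needs >= 4 tab-separated columns")
  n_sample <- ncol(dt) - 3L
  pos <- suppressWarnings(as.integer(dt[[2]]))
  if (anyNA(pos))
    stop("non-integer position at line ", which(is.na(pos))[1])
  ragged <- which(apply(as.matrix(dt[, -(1:3)]), 1, function(r) any(r == "" | is.na(r))))
  if (length(ragged))
    stop("ragged row (missing sample column) at line ", ragged[1])
  counts <- array(NA_integer_, c(nrow(dt), n_sample, 6L))
  for (j in seq_len(n_sample)) {
    parts <- tstrsplit(dt[[j + 3L]], ":", fixed = TRUE)
    if (length(parts) != 6L)
      stop("sample column ", j, " does not have 6 ':'-separated counts")
    for (k in 1:6) {
      v <- suppressWarnings(as.integer(parts[[k]]))
      if (anyNA(v))
        stop("non-numeric count at line ", which(is.na(v))[1],
             ", sample ", j)
      counts[, j, k] <- v
    }
  }
  sync_table(dt[[1]], pos, dt[[3]], counts)
}

#' Write a sync table to file
#'
#' Inverse of [read_sync()]: `write_sync` followed by `read_sync` is the
#' identity on valid tables, and rewriting a freshly read table reproduces the
#' file byte for byte.
#'
#' @param x A [sync_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "sync_table"))
  cols <- list(x$chrom, x$pos, x$ref)
  for (j in seq_len(n_samples(x))) {
    m <- x$counts[, j, , drop = FALSE]
    cols[[j + 3L]] <- paste(m[, 1, 1], m[, 1, 2], m[, 1, 3], m[, 1, 4],
                            m[, 1, 5], m[, 1, 6], sep = ":")
  }
  fwrite(cols, path, sep = "\t", col.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Biallelic major/minor reduction of a sync table
#'
#' Determines the major and minor allele of every SNP jointly across all
#' samples (ties broken toward the alphabetically first nucleotide, N and
#' deletion counts ignored) and returns per-sample read counts for the two
#' alleles.
#'
#' @param x A [sync_table].
#' @return A list with elements `major`, `minor` (nucleotide per SNP),
#'   `major_counts`, `minor_counts`, `coverage` (matrices `[snp x sample]`,
#'   coverage counting the two focal alleles only) and `freq`
#'   (minor-allele read frequency, `NaN` where coverage is 0).
#' @export
allele_counts <- function(x) {
  stopifnot(inherits(x, "sync_table"))
  nuc <- c("A", "C", "G", "T")                    # alphabetical tie order
  idx <- match(nuc, SYNC_ALLELES)
  tot <- apply(x$counts[, , idx, drop = FALSE], c(1, 3), sum)
  if (n_snps(x) == 0) {
    m <- matrix(integer(0), 0, n_samples(x))
    return(list(major = character(0), minor = character(0), major_counts = m,
                minor_counts = m, coverage = m, freq = m))
  }
  ord <- apply(tot, 1, order, decreasing = TRUE)  # ties keep alphabetical order
  maj <- nuc[ord[1, ]]
  mino <- nuc[ord[2, ]]
  n <- n_snps(x)
  major_counts <- minor_counts <- matrix(0L, n, n_samples(x))
  for (j in seq_len(n_samples(x))) {
    sl <- x$counts[, j, idx, drop = FALSE]
    major_counts[, j] <- sl[cbind(seq_len(n), 1L, ord[1, ])]
    minor_counts[, j] <- sl[cbind(seq_len(n), 1L, ord[2, ])]
  }
  cov <- major_counts + minor_counts
  list(major = maj, minor = mino, major_counts = major_counts,
       minor_counts = minor_counts, coverage = cov,
       freq = minor_counts / cov)
}

#' Build a biallelic sync table from minor-allele counts
#'
#' Convenience constructor for simulated data: the major allele is written
#' as `A` (also the reference) and the minor allele as `C`.
#'
#' @param chrom Chromosome label (scalar or per SNP).
#' @param pos 1-based positions, strictly increasing.
#' @param minor_counts,coverage Matrices `[snp x sample]` of minor-allele
#'   reads and total depths.
#' @return A [sync_table].
#' @export
sync_from_counts <- function(chrom, pos, minor_counts, coverage) {
  n <- length(pos)
  ns <- ncol(minor_counts)
  counts <- array(0L, c(n, ns, 6L))
  counts[, , 1] <- as.integer(coverage - minor_counts)  # A = major
  counts[, , 3] <- as.integer(minor_counts)             # C = minor
  sync_table(chrom, pos, rep("A", n), counts)
}
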