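# Shared helpers: independent oracles and tiny fixture builders.

# deterministic selection recursion (infinite-population oracle)
det_recursion <- function(p0, s, generations) {
  p <- p0
  for (i in seq_len(generations))
    p <- p * (p * (1 + s) + (1 - p) * (1 + s / 2)) / (1 + s * p)
  p
}

# brute-force CMH statistic from hypergeometric moments, one 2x2xK table
cmh_oracle <- function(a, b, c_, d) {
  n1 <- a + b; n2 <- c_ + d; m1 <- a + c_; m2 <- b + d; tt <- n1 + n2
  ea <- n1 * m1 / tt
  va <- n1 * n2 * m1 * m2 / (tt^2 * (tt - 1))
  sum(a - ea)^2 / sum(va)
}

# small two-sample sync table from minor counts/coverages
toy_sync <- function(minor, coverage, chrom = "2R") {
  minor <- rbind(minor); coverage <- rbind(coverage)
  thermoevolve::sync_table(
    chrom, seq_len(nrow(minor)) * 10L, rep("A", nrow(minor)),
    {
      cnt <- array(0L, c(nrow(minor), ncol(minor), 6L))
      cnt[, , 1] <- coverage - minor
      cnt[, , 3] <- minor
      cnt
    })
}
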