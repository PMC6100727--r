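test_that("candidate filter is conjunctive over replicates and samples", {
  # SNP 1 rises 0.3 in four replicates, 0.1 in one -> excluded
  # SNP 2 rises 0.3 everywhere -> kept; SNP 3 kept but one sample at depth 19
  anc <- matrix(0.4, 3, 5)
  evo <- rbind(c(0.7, 0.7, 0.7, 0.7, 0.5), matrix(0.7, 2, 5))
  cov <- matrix(100L, 3, 10); cov[3, 2] <- 19L
  x <- structure(list(chrom = rep("2R", 3), pos = c(10L, 20L, 30L),
                      anc_freq = anc, evo_freq = evo, coverage = cov),
                 class = "er_dataset")
  cand <- filter_candidates(x, block_params())
  expect_equal(cand$pos, 20L)
  expect_equal(unname(cand$start_freq), 0.4)
})

test_that("falling alleles are polarised to the rising variant", {
  anc <- rbind(rep(0.8, 5)); evo <- rbind(rep(0.45, 5))
  x <- structure(list(chrom = "2R", pos = 1L, anc_freq = anc, evo_freq = evo,
                      coverage = matrix(50L, 1, 10)), class = "er_dataset")
  cand <- filter_candidates(x, block_params())
  expect_equal(length(cand$pos), 1L)
  expect_equal(unname(cand$start_freq), 0.2)
  expect_true(all(cand$rise > 0))
})

test_that("identical trajectories form one fully correlated block", {
  traj <- c(0.4, 0.42, 0.38, 0.41, 0.39, 0.8, 0.82, 0.78, 0.83, 0.77)
  cand <- structure(list(chrom = rep("2R", 2), pos = c(100L, 200L),
                         start_freq = c(0.4, 0.4),
                         rise = matrix(0.4, 2, 5),
                         traj = rbind(traj, traj)),
                    class = "candidate_set")
  blocks <- cluster_trajectories(cand, block_params())
  expect_length(blocks, 1L)
  expect_equal(blocks[[1]]$pos, c(100L, 200L))
})

test_that("independent noise-only trajectories rarely cluster", {
  set.seed(61)
  linked <- replicate(500, {
    cand <- structure(list(chrom = rep("2R", 2), pos = c(1L, 2L),
                           start_freq = c(0.4, 0.4),
                           rise = matrix(0.3, 2, 5),
                           traj = matrix(rnorm(20, 0.5, 0.05), 2, 10)),
                      class = "candidate_set")
    length(cluster_trajectories(cand, block_params())) > 0
  })
  expect_lte(mean(linked), 0.05)
})

test_that("planted block is recovered against a neutral background", {
  sc <- generate_scan(scan_scenario(n_snps = 200,
                                    blocks = list(planted_block(28))),
                      seed = 71)
  er <- er_dataset(sc$ancestral, sc$evolved)
  cand <- filter_candidates(er, block_params())
  truth <- sc$truth$pos[sc$truth$selected]
  # every planted SNP passes the diagnostic filter (ascertained design) and
  # at least 90% of neutral SNPs are removed
  expect_true(all(truth %in% cand$pos))
  neutral_kept <- sum(!(cand$pos %in% truth))
  expect_lte(neutral_kept, 0.1 * (200 - 28))
  blocks <- cluster_trajectories(cand, block_params())
  big <- blocks[[which.max(vapply(blocks, function(b) length(b$pos), 0L))]]
  jaccard <- length(intersect(big$pos, truth)) /
    length(union(big$pos, truth))
  expect_gte(jaccard, 0.9)
})

test_that("block calls are invariant to SNP and replicate permutations", {
  sc <- generate_scan(scan_scenario(n_snps = 120,
                                    blocks = list(planted_block(15))),
                      seed = 72)
  er <- er_dataset(sc$ancestral, sc$evolved)
  b1 <- cluster_trajectories(filter_candidates(er), block_params())
  set.seed(73)
  perm <- sample(n_snps(sc$ancestral))
  ord <- order(perm)
  er2 <- structure(list(chrom = er$chrom[perm][ord], pos = er$pos[perm][ord],
                        anc_freq = er$anc_freq[perm, ][ord, ],
                        evo_freq = er$evo_freq[perm, ][ord, ],
                        coverage = er$coverage[perm, ][ord, ]),
                   class = "er_dataset")
  rep_perm <- sample(5)
  er3 <- structure(list(chrom = er$chrom, pos = er$pos,
                        anc_freq = er$anc_freq[, rep_perm],
                        evo_freq = er$evo_freq[, rep_perm],
                        coverage = er$coverage),
                   class = "er_dataset")
  for (er_alt in list(er2, er3)) {
    b2 <- cluster_trajectories(filter_candidates(er_alt), block_params())
    expect_equal(lapply(b1, function(b) b$pos), lapply(b2, function(b) b$pos))
  }
})

test_that("raising the correlation threshold only refines blocks", {
  sc <- generate_scan(scan_scenario(n_snps = 150,
                                    blocks = list(planted_block(20))),
                      seed = 74)
  cand <- filter_candidates(er_dataset(sc$ancestral, sc$evolved))
  sizes <- vapply(c(0.8, 0.9, 0.95, 0.99), function(th) {
    b <- cluster_trajectories(cand, block_params(min_correlation = th))
    if (length(b)) max(vapply(b, function(x) length(x$pos), 0L)) else 0L
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("BED export converts 1-based inclusive spans to 0-based half-open", {
  b <- list(structure(list(chrom = "3R", pos = c(4239638L, 4271390L),
                           mean_start_freq = 0.44, mean_rise = rep(0.4, 5)),
                      class = "haplotype_block"))
  bed <- blocks_to_bed(b)
  expect_equal(bed$start, 4239637L)
  expect_equal(bed$end, 4271390L)
})
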