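test_that("CMH statistic matches the hypergeometric oracle on single tables", {
  # a=30, b=10 / c=10, d=30: strong association in one stratum
  res <- cmh_test(30, 10, 10, 30)
  expect_equal(res$statistic, cmh_oracle(30, 10, 10, 30), tolerance = 1e-12)
  expect_equal(res$n_strata, 1L)
  # no association: identical 50:50 margins in five strata
  res <- cmh_test(rep(50, 5), rep(50, 5), rep(50, 5), rep(50, 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # equal association in opposite directions cancels
  res <- cmh_test(c(30, 10), c(10, 30), c(10, 30), c(30, 10))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
})

test_that("CMH agrees with mantelhaen.test on random tables", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    a <- rpois(k, 30) + 1; b <- rpois(k, 30) + 1
    c_ <- rpois(k, 30) + 1; d <- rpois(k, 30) + 1
    tbl <- array(rbind(a, b, c_, d), dim = c(2, 2, k))
    ref <- stats::mantelhaen.test(tbl, correct = FALSE)
    res <- cmh_test(a, b, c_, d)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("zero-margin strata are dropped; empty tables error", {
  expect_warning(res <- cmh_test(c(30, 0), c(10, 0), c(10, 0), c(30, 0)),
                 "zero-margin")
  expect_equal(res$n_strata, 1L)
  expect_error(suppressWarnings(cmh_test(0, 0, 0, 0)), "zero margin")
})

test_that("conservative merge keeps the least significant track", {
  mk <- function(p) structure(data.frame(statistic = qchisq(p, 1, lower.tail = FALSE),
                                         p_value = p, n_strata = 5L),
                              class = c("cmh_result", "data.frame"))
  out <- conservative_merge(list(mk(1e-8), mk(1e-3), mk(0.2)))
  expect_equal(out$p_value, 0.2)
  expect_identical(conservative_merge(list(mk(0.01))), mk(0.01))
  out <- conservative_merge(list(mk(0.5), mk(0.5)))
  expect_equal(out$p_value, 0.5)
  expect_error(conservative_merge(list()), "at least one")
  # never more significant than any input
  set.seed(3)
  tracks <- lapply(1:3, function(i) mk(runif(20)))
  merged <- conservative_merge(tracks)
  for (tr in tracks) expect_true(all(merged$p_value >= tr$p_value))
})

test_that("SNP filter enforces per-sample coverage and minor-read rules", {
  counts <- list(minor_counts = rbind(c(5, 5), c(0, 5), c(5, 5), c(5, 5)),
                 coverage = rbind(c(50, 50), c(50, 50), c(4, 50), c(50, 501)))
  expect_equal(snp_filter(counts), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("ancestral reads split multinomially into balanced pseudo-replicates", {
  sp <- split_ancestral(minor = c(100L, 40L), major = c(300L, 360L), k = 5,
                        seed = 8)
  expect_equal(rowSums(sp$minor), c(100L, 40L))
  expect_equal(rowSums(sp$major), c(300L, 360L))
  expect_equal(dim(sp$minor), c(2L, 5L))
  # expectation per pseudo-replicate is total/k
  big <- split_ancestral(5000L, 15000L, k = 5, seed = 9)
  expect_equal(as.vector(big$minor), rep(1000, 5), tolerance = 0.1)
})

test_that("FPR calibration self-calibrates on neutral data and hits zero below the minimum", {
  set.seed(21)
  sc <- generate_scan(scan_scenario(n_snps = 2000, blocks = list()), seed = 22)
  scan <- cmh_scan(sc$ancestral, sc$evolved)
  cal <- calibrate_fpr(scan$p_value, p0 = scan$anc_freq, ne = 219,
                       generations = 59, coverage = 80, n_runs = 3,
                       thresholds = c(0.2, 0.05, 0.01), seed = 23)
  expect_true(all(cal$fpr > 0.7 & cal$fpr < 1.4))
  # a threshold below every simulated and empirical p-value
  cal0 <- calibrate_fpr(c(0.5, 1e-300), p0 = scan$anc_freq, ne = 219,
                        generations = 59, coverage = 80, n_runs = 2,
                        thresholds = 1e-280, seed = 24)
  expect_equal(cal0$fpr, 0)
  # no empirical discoveries -> FPR undefined, not zero
  cal_na <- calibrate_fpr(rep(0.9, 100), p0 = scan$anc_freq, ne = 219,
                          generations = 59, coverage = 80, n_runs = 2,
                          thresholds = 1e-4, seed = 25)
  expect_true(is.na(cal_na$fpr))
})
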