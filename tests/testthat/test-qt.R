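test_that("mean phenotype reproduces the printed anchors", {
  # 8 background loci of equal effect summing to 0.5; normalisation makes the
  # anchor independent of the background count
  for (nb in c(8L, 80L, 500L)) {
    m <- qt_model(nb, optimum = 0.5)
    z0 <- mean_phenotype(m, c(0.44, 0.20, rep(0.14, nb)))
    expect_equal(round(z0, 2), 0.18)
    zfix <- mean_phenotype(m, c(1, 1, rep(0.14, nb)))
    expect_equal(round(zfix, 2), 0.32)
  }
  m <- qt_model(10, 0.5)
  expect_equal(mean_phenotype(m, rep(0, 12)), 0)
  expect_equal(mean_phenotype(m, rep(1, 12)), 1)
  expect_error(mean_phenotype(m, rep(0.5, 5)), "one frequency per locus")
})

test_that("bounded Gaussian fitness has the stated shape", {
  m <- qt_model(10, optimum = 0.5)
  expect_equal(qt_fitness(0.5, m), 1.5)
  expect_equal(qt_fitness(5, m), 0.5, tolerance = 1e-6)
  expect_equal(qt_fitness(0.5 + 0.2, m), 0.5 + exp(-1 / 2), tolerance = 1e-12)
  expect_equal(qt_fitness(0.3, m), qt_fitness(0.7, m))
})

test_that("proportion explained is 1 without background loci and invariant to effect rescaling", {
  m <- qt_model(0, optimum = 0.5)
  out <- run_qt_simulation(m, seed = 81)
  expect_equal(out$proportion_explained, 1)
  # rescaling all raw effects leaves normalised dynamics unchanged
  m1 <- qt_model(10, 0.5, focal_effects = c(0.07, 0.06),
                 background_total_effect = 0.5,
                 background_p0 = rep(0.14, 10))
  m2 <- qt_model(10, 0.5, focal_effects = 10 * c(0.07, 0.06),
                 background_total_effect = 5,
                 background_p0 = rep(0.14, 10))
  expect_equal(m1$effects, m2$effects)
  o1 <- run_qt_simulation(m1, seed = 82)
  o2 <- run_qt_simulation(m2, seed = 82)
  expect_equal(o1$proportion_explained, o2$proportion_explained)
})

test_that("selection toward a distant optimum drives the focal contribution up", {
  # each replicate's combined focal contribution to the phenotype must rise
  # (individual loci can equilibrate once their homozygote overshoots)
  set.seed(83)
  up <- replicate(50, {
    m <- qt_model(0, optimum = 0.7)
    out <- run_qt_simulation(m)
    rises <- (out$final_frequencies - out$initial_frequencies) %*%
      m$effects[1:2]
    all(rises > 0)
  })
  expect_gte(mean(up), 0.99)
})

test_that("an optimum below the initial phenotype does not drive alleles up", {
  set.seed(84)
  d <- replicate(50, {
    m <- qt_model(20, optimum = 0.05, background_p0 = rep(0.14, 20))
    run_qt_simulation(m)$delta_p[1]
  })
  expect_lte(mean(d > 0), 0.5)
  expect_lt(mean(d), 0)
})

test_that("flat fitness reduces the model to pure drift", {
  set.seed(85)
  m <- qt_model(0, optimum = 0.5, fitness_min = 1, fitness_max = 1,
                generations = 20, n_replicates = 200)
  out <- run_qt_simulation(m)
  drift <- abs(out$final_frequencies - out$initial_frequencies)
  # neutral WF expectation of |delta p| over 19 generations at N = 219
  p_exp <- replicate(2, abs(simulate_drift(
    rep(c(0.44, 0.20), each = 1000), 219, 19) - rep(c(0.44, 0.20), each = 1000)))
  expect_equal(mean(drift), mean(p_exp), tolerance = 0.15)
})

test_that("the simulation grid flags experiment-consistent cells sensibly", {
  grid <- run_qt_grid(c(10, 500), c(0.4, 0.6), n_sims = 6,
                      cmh_cutoff = 1e-20, seed = 86)
  expect_equal(nrow(grid), 4L)
  expect_true(all(grid$mean_proportion >= 0 & grid$mean_proportion <= 1))
  expect_true(all(grid$focal_detection >= 0 & grid$focal_detection <= 1))
  # many small background loci: high proportion explained, no background hits
  many <- grid[grid$n_background == 500, ]
  few <- grid[grid$n_background == 10, ]
  expect_gt(min(many$mean_proportion), max(few$mean_proportion))
})

test_that("detection cutoff calibration tracks the drift-null tail", {
  cut1 <- calibrate_detection_cutoff(n_snps = 2e4, top_k = 100,
                                     n_tests = 2741793, seed = 87)
  cut2 <- calibrate_detection_cutoff(n_snps = 2e4, top_k = 2000,
                                     n_tests = 2741793, seed = 87)
  expect_lt(cut1, cut2)   # stricter rule, smaller p cutoff
  expect_lt(cut1, 1e-10)
})
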