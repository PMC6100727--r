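test_that("temporal Ne estimator recovers the truth and scales correctly", {
  set.seed(31)
  sim_design <- function(ne, n_snps = 4000, t = 59, cov = 200, pool = 500) {
    p0 <- sfs_sample(n_snps)
    pt <- simulate_drift(p0, ne, t)
    x <- rbinom(n_snps, cov, rbinom(n_snps, pool, p0) / pool) / cov
    y <- rbinom(n_snps, cov, rbinom(n_snps, pool, pt) / pool) / cov
    estimate_ne(x, y, cov, cov, pool, t)$ne
  }
  expect_equal(sim_design(219), 219, tolerance = 0.12)
  # doubling the true Ne roughly doubles the estimate
  ratio <- sim_design(400) / sim_design(200)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})

test_that("Ne rank order is preserved between nested simulations", {
  set.seed(33)
  wins <- 0L
  for (i in 1:40) {
    p0 <- sfs_sample(400)
    est <- vapply(c(100, 1000), function(ne) {
      pt <- simulate_drift(p0, ne, 30)
      x <- rbinom(400, 150, p0) / 150
      y <- rbinom(400, 150, pt) / 150
      estimate_ne(x, y, 150, 150, 500, 30)$ne
    }, 0)
    if (est[1] < est[2]) wins <- wins + 1L
  }
  expect_gte(wins, 38L)
})

test_that("Ne is unidentifiable when drift signal is below sampling noise", {
  p <- runif(200, 0.2, 0.8)
  expect_error(estimate_ne(p, p, 100, 100, 500, 59), "unidentifiable")
})

test_that("exact WF transition matrix rows sum to one", {
  for (s in c(0, 0.07, -0.1)) {
    tm <- wf_transition_matrix(50, s)
    expect_equal(rowSums(tm), rep(1, 101), tolerance = 1e-12)
    expect_equal(tm[1, 1], 1)      # loss absorbing
    expect_equal(tm[101, 101], 1)  # fixation absorbing
  }
})

test_that("selection-coefficient worked examples and the neutral edge", {
  grid <- seq(0, 0.12, by = 0.001)
  tr <- trajectory(rbind(c(0.44, 0.86)), coverages = rbind(c(100, 100)),
                   generations = c(0, 60))
  est <- estimate_s(tr, ne = 219, s_grid = grid)
  expect_equal(round(est$s_hat, 2), 0.07)
  expect_true(est$ci[1] <= est$s_hat && est$s_hat <= est$ci[2])
  expect_equal(est$s_hat, grid[which.max(est$log_likelihood)])

  tr2 <- trajectory(rbind(c(0.20, 0.60)), coverages = rbind(c(100, 100)),
                    generations = c(0, 60))
  expect_equal(round(estimate_s(tr2, ne = 219, s_grid = grid)$s_hat, 2), 0.06)

  # constant trajectory: the grid point nearest zero wins
  tr0 <- trajectory(rbind(c(0.5, 0.5)), coverages = rbind(c(200, 200)),
                    generations = c(0, 30))
  est0 <- estimate_s(tr0, ne = 150, s_grid = seq(-0.05, 0.05, by = 0.005))
  expect_equal(est0$s_hat, 0)
})

test_that("estimate_s is nearly unbiased over simulated trajectories", {
  grid <- seq(-0.06, 0.15, by = 0.002)
  for (s_true in c(0, 0.03, 0.07)) {
    traj <- simulate_trajectory(
      wf_params(ne = 219, s = s_true, generations = 60, p0 = 0.44),
      n_replicates = 200, seed = 400 + round(1000 * s_true))
    tr <- trajectory(traj$frequencies[, c(1, 61)],
                     coverages = matrix(1000L, 200, 2),
                     generations = c(0, 60))
    s_hat <- estimate_s(tr, ne = 219, s_grid = grid,
                        combine = "per_replicate")
    expect_lt(abs(mean(s_hat) - s_true), 0.01)
  }
})

test_that("pooled replicate likelihood is the sum of per-replicate curves", {
  grid <- seq(0, 0.12, by = 0.002)
  traj <- simulate_trajectory(wf_params(ne = 219, s = 0.07, generations = 60,
                                        p0 = 0.44),
                              n_replicates = 5, seed = 55, coverage = 100)
  est <- estimate_s(traj, ne = 219, s_grid = grid)
  expect_equal(est$s_hat, 0.07, tolerance = 0.5)
  single <- lapply(1:5, function(r) estimate_s(
    trajectory(traj$frequencies[r, c(1, 61), drop = FALSE],
               coverages = traj$coverages[r, c(1, 61), drop = FALSE],
               generations = c(0, 60)), ne = 219, s_grid = grid))
  expect_equal(est$log_likelihood,
               Reduce(`+`, lapply(single, function(e) e$log_likelihood)),
               tolerance = 1e-10)
  expect_error(estimate_s(traj, ne = 219, s_grid = numeric(0)), "empty")
  expect_error(estimate_s(traj, ne = 5000), "too large")
})
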