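test_that("discounted action values follow the closed form", {
  p <- vigour_problem(a = -1, gamma = 0.98)
  expect_equal(q_gamma(p, 5), -0.2 + 0.98^5, tolerance = 1e-12)
  # no cost: strictly decreasing in tau
  p0 <- vigour_problem(a = 0, gamma = 0.9)
  taus <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(q_gamma(p0, taus)) < 0))
  # both terms vanish for very long latencies
  expect_lt(abs(q_gamma(p, 1e6)), 1e-5)
  expect_error(q_gamma(p, 0), "positive")
})

test_that("the cost bound matches its analytic form and brackets solvability", {
  expect_equal(a_min(0.98), 4 / (exp(2) * log(0.98)), tolerance = 1e-15)
  expect_lt(abs(a_min(0.98) - (-26.79547)), 1e-4)
  expect_error(a_min(1), "gamma")
  # gamma -> 1: acting is always worthwhile in the limit
  expect_lt(a_min(1 - 1e-10), -1e9)

  for (g in c(0.9, 0.95, 0.98)) {
    below <- optimal_latency(vigour_problem(a_min(g) * 1.01, g))
    above <- optimal_latency(vigour_problem(a_min(g) * 0.99, g))
    expect_true(is.na(below$tau_star))
    expect_true(is.finite(above$tau_star))
    # first-order condition |a| = tau^2 gamma^tau |log gamma| has a root
    # exactly when the cost is above the bound
    f_max <- max(seq(0.1, 500, by = 0.01)^2 * g^seq(0.1, 500, by = 0.01) *
                   abs(log(g)))
    expect_equal(f_max, abs(a_min(g)), tolerance = 1e-4)
  }
})

test_that("the optimiser agrees with brute-force grid search", {
  g <- 0.98
  t1 <- optimal_latency(vigour_problem(-1, g))$tau_star
  t4 <- optimal_latency(vigour_problem(-4, g))$tau_star
  expect_gt(t4, t1) # costlier vigour defers the press
  taus <- exp(seq(log(1e-3), log(500), length.out = 1e4))
  set.seed(14)
  for (i in 1:20) {
    a <- -runif(1, 0.1, 8)
    gm <- runif(1, 0.85, 0.995)
    got <- optimal_latency(vigour_problem(a, gm))$tau_star
    want <- grid_local_argmax(a, gm, taus)
    if (a < a_min(gm)) {
      expect_true(is.na(got))
    } else {
      step <- want * (log(500 / 1e-3) / 1e4)
      expect_lt(abs(got - want), 2 * step + 1e-3)
    }
  }
})

test_that("future opportunities barely matter at long intervals and hasten pressing at short ones", {
  d30 <- delta_tau_star(-1, 0.9, tau_I = 30)
  expect_lt(abs(d30$delta_tau_star), 0.05)
  d1 <- delta_tau_star(-1, 0.9, tau_I = 1)
  expect_lt(d1$delta_tau_star, 0)
  # the continuing fixed point satisfies its own Bellman equation tightly
  cont <- optimal_latency(vigour_problem(-1, 0.9, chain = "continuing", tau_I = 1))
  expect_lt(cont$residual, 1e-10)
  expect_true(cont$converged)
})

test_that("quasi-tonic ramps peak at (1 - gamma) r regardless of trajectory length", {
  ker <- drf_kernel(dt = 0.01)
  r10 <- quasi_tonic_trace(synth_trajectory(10, post = 0), 0.98, ker)
  r20 <- quasi_tonic_trace(synth_trajectory(20, post = 0), 0.98, ker)
  expect_equal(max(r10$quasi_tonic), 0.02 * 1, tolerance = 1e-14)
  expect_identical(max(r10$quasi_tonic), max(r20$quasi_tonic))
  expect_true(all(r10$quasi_tonic >= 0 & r10$quasi_tonic <= 0.02 + 1e-15))

  # doubling the reward doubles the whole trace pointwise
  rbig <- quasi_tonic_trace(synth_trajectory(10, r = 2, post = 0), 0.98, ker)
  expect_equal(rbig$quasi_tonic, 2 * r10$quasi_tonic, tolerance = 1e-15)
  expect_error(
    quasi_tonic_trace(
      structure(tibble::tibble(time_s = c(0, 0.01), proximity = c(1, -1)),
                class = c("ramp_trajectory", "tbl_df", "tbl", "data.frame")),
      0.98),
    "non-negative"
  )
})

test_that("the quasi-tonic signal tracks goal proximity", {
  traj <- synth_trajectory(8, type = "pause_retreat", dt = 0.01,
                           pause_at = 3, pause_len = 1.5, retreat_len = 1)
  res <- quasi_tonic_trace(traj, 0.98)
  step <- round(1 / 0.01)
  dprox <- diff(traj$proximity)[seq_len(nrow(res) - 1L) + step]
  dqt <- diff(res$quasi_tonic)
  expect_true(all(dqt[dprox < 0] > 0))          # approach: signal rises
  expect_true(all(abs(dqt[dprox == 0]) < 1e-15)) # pause: signal flat
  expect_true(all(dqt[dprox > 0] < 0))          # retreat: signal falls
})

test_that("the undiscounted error averages to the quasi-tonic signal on goal-directed runs", {
  for (dur in c(6, 15)) {
    res <- quasi_tonic_trace(synth_trajectory(dur, post = 0), 0.98)
    expect_lt(abs(mean(res$delta_A) - mean(res$quasi_tonic)), 1e-10)
  }
})

test_that("convolution smooths and delays the ramp", {
  res <- quasi_tonic_trace(synth_trajectory(10, post = 0), 0.98)
  expect_lte(max(res$da), max(res$quasi_tonic) + 1e-12)
  expect_gte(res$time_s[which.max(res$da)], res$time_s[which.max(res$quasi_tonic)])
})

test_that("scaled discounted values converge to the cycle-average reward", {
  gaps <- purrr::map_dbl(c(0.9, 0.99, 0.999), function(g) {
    attr(cycle_chain_values(c(1, 0, 2), g), "gap")
  })
  expect_true(all(diff(gaps) < 0))
  expect_equal(attr(cycle_chain_values(c(1, 0, 2), 0.999), "rho"), 1)
})
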