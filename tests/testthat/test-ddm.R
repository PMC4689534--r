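test_that("the tonic gain process has the right degenerate and stationary behaviour", {
  # no noise: the gain stays at its long-term mean
  g0 <- simulate_ou(ou_params(theta = 1.3, sigma = 0), duration = 2, seed = 1)
  expect_true(all(g0$value == 1.3))
  expect_equal(g0$value[1L], 1.3) # g(0) = theta

  # stationary mean and variance over a long path
  p <- ou_params(theta = 1, kappa = 0.01, sigma = 0.1, dt = 0.01)
  g <- simulate_ou(p, duration = 2000, seed = 2)
  v_stat <- p$sigma^2 / (2 * p$kappa - p$kappa^2)
  expect_lt(abs(mean(g$value) - p$theta), 0.1 * p$theta)
  expect_lt(abs(var(g$value) / v_stat - 1), 0.1)
})

test_that("noise-free trials cross at z / (g A), with sub-step interpolation", {
  ou <- ou_params(theta = 1, sigma = 0)
  tr <- simulate_trial(ou, ddm_params(A = 1, c = 0, z = 5))
  expect_equal(tr$crossing_time, 5, tolerance = 0.011)
  expect_equal(tr$sign, 1)
  # doubling the gain halves the crossing time (gain scales the drift)
  tr2 <- simulate_trial(ou_params(theta = 2, sigma = 0), ddm_params(1, 0, 5))
  expect_equal(tr2$crossing_time, 2.5, tolerance = 0.011)
  # the decision variable is clamped at the threshold
  expect_equal(max(abs(tr$x_path$value)), 5)
})

test_that("unit gain reduces the process to the plain drift-diffusion model", {
  ou <- ou_params(theta = 1, kappa = 0, sigma = 0, dt = 0.01)
  ddm <- ddm_params(A = 0.5, c = 1, z = 3)
  tr <- simulate_trial(ou, ddm, seed = 21, max_duration = 60)
  # replay the same noise stream through the unmodulated update
  set.seed(21)
  eps <- rnorm(6000)
  x <- cumsum(ddm$A * 0.01 + ddm$c * sqrt(0.01) * eps)
  m <- length(tr$x_path$value) - 2L # drop x(0) and the clamped final sample
  expect_equal(tr$x_path$value[-1L][seq_len(m)], x[seq_len(m)],
               tolerance = 1e-12)
})

test_that("constant-gain ensembles match closed-form mean decision time and error rate", {
  ou <- ou_params(theta = 1, sigma = 0)
  ens <- run_ensemble(ou, ddm_params(A = 1, c = 1, z = 5), n = 3000, seed = 3,
                      max_duration = 40)
  ok <- ens$trials$crossed
  dtm <- mean(ens$trials$crossing_time_s[ok])
  se <- sd(ens$trials$crossing_time_s[ok]) / sqrt(sum(ok))
  expect_lt(abs(dtm - ddm_mean_dt(1, 1, 5)), 3 * se)

  # error-rate oracle at a low threshold (fine grid keeps the discrete
  # barrier-crossing bias well inside the Monte-Carlo band)
  ens_e <- run_ensemble(ou_params(theta = 1, sigma = 0, dt = 0.002),
                        ddm_params(A = 1, c = 1, z = 1), n = 2000, seed = 3,
                        max_duration = 40)
  oke <- ens_e$trials$crossed
  er <- mean(ens_e$trials$sign[oke] == -1)
  p_err <- 1 / (1 + exp(2 * 1 * 1 / 1^2))
  expect_lt(abs(er - p_err), 3 * sqrt(p_err * (1 - p_err) / sum(oke)))

  # gain scaling: with g = theta both drift and noise scale, so the mean
  # decision time follows the rescaled closed form
  ens2 <- run_ensemble(ou_params(theta = 2, sigma = 0, dt = 0.002),
                       ddm_params(1, 1, 5), n = 800, seed = 4,
                       max_duration = 40)
  ok2 <- ens2$trials$crossed
  dtm2 <- mean(ens2$trials$crossing_time_s[ok2])
  se2 <- sd(ens2$trials$crossing_time_s[ok2]) / sqrt(sum(ok2))
  expect_lt(abs(dtm2 - ddm_mean_dt(1, 1, 5, g = 2)), 3 * se2)
})

test_that("raising tonic dopamine speeds decisions", {
  ddm <- ddm_params(A = 1, c = 1, z = 5)
  med <- purrr::map_dbl(c(1, 1.5, 2), function(th) {
    ens <- run_ensemble(ou_params(theta = th, kappa = 0.01, sigma = 0.05),
                        ddm, n = 400, seed = 5)
    median(ens$trials$crossing_time_s, na.rm = TRUE)
  })
  expect_true(all(diff(med) < 0))
})

test_that("ensembles are seed-reproducible and censor non-crossing trials", {
  ou <- ou_params()
  ddm <- ddm_params(A = 2, c = 0.1, z = 5)
  ph <- phasic_spec(mu = 4, sd = 1, time = 1)
  e1 <- run_ensemble(ou, ddm, ph, n = 100, seed = 8)
  e2 <- run_ensemble(ou, ddm, ph, n = 100, seed = 8)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$corr, e2$corr)
  expect_true(is.finite(e1$corr))

  # a tiny threshold-free horizon censors everything; correlation is absent
  slow <- run_ensemble(ou_params(theta = 0.01, sigma = 0), ddm_params(0.01, 0, 5),
                       n = 3, seed = 1, max_duration = 1)
  expect_identical(slow$n_censored, 3L)
  expect_true(is.na(slow$corr))
})

test_that("crossing-aligned tonic gain ramps toward the decision", {
  ens <- run_ensemble(ou_params(), ddm_params(A = 1, c = 1, z = 5),
                      n = 400, seed = 12)
  al <- ens$aligned
  last2 <- al$mean[al$time_s >= -2]
  # increasing trend over the final two seconds before crossing
  fit <- coef(lm(last2 ~ seq_along(last2)))[2L]
  expect_gt(fit, 0)
  expect_gt(al$mean[al$time_s == 0], al$mean[1L])
})
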