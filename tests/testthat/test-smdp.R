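test_that("cycle average reward follows the renewal-reward ratio", {
  spec <- lever_task(a = -1, b = 0, r = 1, tau_post = 0.5, tau_I = 30)
  expect_equal(as.numeric(cycle_average_reward(spec, timing_fixed(1))), 0)
  expect_equal(as.numeric(cycle_average_reward(spec, timing_fixed(2))),
               0.5 / 32.5, tolerance = 1e-12)
  # no utilities, no reward rate
  spec0 <- lever_task(a = 0, b = 0, r = 1e-12, tau_I = 30)
  expect_equal(as.numeric(cycle_average_reward(spec0, timing_gamma(2, 1))),
               1e-12 / 32.5, tolerance = 1e-6)
  # E[1/T] diverges for shape <= 1 unless the cost is truncated
  spec_bad <- lever_task(cost_floor = 0)
  expect_error(cycle_average_reward(spec_bad, timing_gamma(1, 1)), "truncate")
})

test_that("all-zero utilities give zero rho and zero relative values", {
  spec <- lever_task(a = 0, b = 0, r = 1e-300, tau_I = 30)
  tab <- solve_relative_values(spec, timing_gamma(2, 1))
  expect_lt(abs(tab$rho), 1e-12)
  expect_lt(max(abs(tab$v1)), 1e-12)
  expect_lt(abs(tab$v2), 1e-12)
})

test_that("solved relative values satisfy the consistency recursion at every gridpoint", {
  spec <- lever_task()
  for (mode in list(comm_indirect(), comm_direct())) {
    tab <- solve_relative_values(spec, timing_gamma(2, 1), mode)
    expect_lt(max(abs(rv_residual(tab))), 1e-8)
  }
})

test_that("constant hazard makes microstate values flat; sampling oracle agrees", {
  spec <- lever_task()
  tab <- solve_relative_values(spec, timing_gamma(1, 1))
  # flat within the plotted range (away from the truncation horizon)
  v <- tab$v1[tab$t_grid <= 10]
  expect_lt(max(v) - min(v), 1e-6)

  # Monte-Carlo relative-value oracle at three gridpoints (both regimes)
  set.seed(31)
  tab2 <- solve_relative_values(spec, timing_gamma(2, 1))
  for (t_hat in c(0, 1, 4)) {
    mc <- mc_relative_value(tab2, t_hat, n = 4e4)
    i <- which.min(abs(tab2$t_grid - t_hat))
    expect_lt(abs(tab2$v1[i] - mc$value), 4 * mc$se + 1e-7)
  }
})

test_that("grid refinement leaves microstate values essentially unchanged", {
  spec1 <- lever_task(dt = 0.01, horizon = 15, cost_floor = 0.01)
  spec2 <- lever_task(dt = 0.005, horizon = 15, cost_floor = 0.01)
  tab1 <- solve_relative_values(spec1, timing_gamma(2, 1))
  tab2 <- solve_relative_values(spec2, timing_gamma(2, 1))
  v2_on_1 <- tab2$v1[seq(1, length(tab2$v1), by = 2L)]
  expect_lt(max(abs(tab1$v1 - v2_on_1)) / max(abs(tab1$v1)), 0.01)
})

test_that("efference transients are flat in T under a constant hazard and shrink under a rising one", {
  spec <- lever_task()
  tab11 <- solve_relative_values(spec, timing_gamma(1, 1))
  tr11 <- purrr::map(c(1, 3, 10), ~ td_trace(tab11, T = .x))
  eff11 <- purrr::map_dbl(tr11, impulse_area, "efference_copy")
  expect_lt(max(eff11) - min(eff11), 1e-6)

  tab21 <- solve_relative_values(spec, timing_gamma(2, 1))
  eff21 <- purrr::map_dbl(c(1, 3, 10), ~ impulse_area(td_trace(tab21, T = .x),
                                                      "efference_copy"))
  expect_true(all(diff(eff21) < 0))

  # press completion sits exactly tau_post after the notification
  expect_equal(tr11[[2]]$press_time_s, 3.5)
  expect_error(td_trace(tab21, T = 1e4), "grid")
})

test_that("direct communication makes press-proximal transients grow with latency", {
  spec <- lever_task()
  tab <- solve_relative_values(spec, timing_gamma(2, 1), comm_direct(k = 0.1))
  press <- purrr::map_dbl(c(1, 3, 10), function(tau) {
    tr <- td_trace(tab, T = tau, tau = tau)
    impulse_area(tr, "efference_copy") + impulse_area(tr, "press")
  })
  expect_true(all(diff(press) > 0))
})

test_that("with a positive opportunity cost the direct signal devalues slower choices", {
  # the direct-signal transient reflects the opportunity cost of the chosen
  # latency, -rho * (E[T | tau] - E[T]); its ordering presupposes rho > 0,
  # so test at a reward making the cycle clearly profitable
  spec <- lever_task(r = 2)
  tab <- solve_relative_values(spec, timing_gamma(2, 1), comm_direct(k = 0.1))
  expect_gt(tab$rho, 0)
  sig <- purrr::map_dbl(c(1, 3, 6, 10), function(tau) {
    impulse_area(td_trace(tab, T = tau, tau = tau), "direct_signal")
  })
  expect_true(all(diff(sig) < 0))
  expect_lt(sig[4L], 0)
})

test_that("phasic errors average to the reward rate over a long session", {
  spec <- lever_task()
  tab <- solve_relative_values(spec, timing_gamma(2, 1))
  set.seed(5)
  n <- 400L
  Ts <- pmin(pmax(sample_timing(tab$timing, n), spec$dt), max(tab$t_grid))
  areas <- purrr::map_dbl(Ts, function(T) {
    tr <- td_trace(tab, T = T)
    sum(tr$delta_p$value) * spec$dt # impulse areas plus the drift integral
  })
  # per-cycle utility over per-cycle duration estimates rho
  cyc <- Ts + spec$tau_post + spec$tau_I
  est <- sum(areas) / sum(cyc)
  u_sd <- sd(areas)
  se <- u_sd / sqrt(n) / mean(cyc)
  expect_lt(abs(est - tab$rho), 3 * se)
})

test_that("waiting-period error is constant in time under a constant hazard", {
  spec <- lever_task()
  tab <- solve_relative_values(spec, timing_gamma(1, 1))
  tr <- td_trace(tab, T = 8)
  inside <- tr$delta_p$time_s > 0.05 & tr$delta_p$time_s < 7.95
  wait <- tr$delta_p$value[inside]
  expect_lt(max(wait) - min(wait), 1e-6)
})

test_that("simulated sessions are reproducible and classify latencies at 5 s", {
  spec <- lever_task()
  tab <- solve_relative_values(spec, timing_gamma(2, 1), comm_direct())
  s1 <- simulate_lever_session(tab, n = 40, seed = 9)
  s2 <- simulate_lever_session(tab, n = 40, seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$cue_aligned$mean, s2$cue_aligned$mean)
  expect_true(all((s1$trials$press_time_s < 5) ==
                    (s1$trials$latency_class == "short")))
  expect_s3_class(tidy(s1), "tbl_df")
  expect_true(all(c("latency_class", "window", "mean", "sem") %in%
                    names(s1$peak_summary)))
})
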