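#' The cued lever-press task
#'
#' Defines the semi-Markov decision process for a cued, self-timed lever
#' press. After a cue (state 1) the actor selects a latency; the critic is
#' notified of the impending press by efference copy at time `T` (entry to
#' state 2, "preparedness to press"); the press completes `tau_post` seconds
#' later (state 3), delivering a reward of utility `r` net of a hyperbolic
#' vigour cost `a / T + b`; a fixed inter-trial interval `tau_I` follows.
#'
#' Because `E[1/T]` diverges for gamma timing with shape <= 1, the hyperbolic
#' cost is evaluated as `a / max(T, cost_floor)`; the default floor is one
#' grid step.
#'
#' @param a Hyperbolic cost factor in utility-seconds (<= 0).
#' @param b Unit press cost in utility (<= 0).
#' @param r Reward utility (> 0).
#' @param tau_post Seconds from efference copy to press completion (>= 0).
#' @param tau_I Inter-trial interval in seconds (>= 0).
#' @param dt Critic time step in seconds (> 0).
#' @param horizon End of the within-trial microstate grid in seconds, or
#'   `NULL` to choose one covering the timing distribution's mass.
#' @param cost_floor Lower truncation of `T` inside the hyperbolic cost
#'   (seconds; defaults to `dt`).
#' @return A list of class `lever_task`.
#' @export
lever_task <- function(a = -1, b = 0, r = 1, tau_post = 0.5, tau_I = 30,
                       dt = 0.01, horizon = NULL, cost_floor = dt) {
  stopifnot(a <= 0, b <= 0, r > 0, tau_post >= 0, tau_I >= 0, dt > 0)
  structure(
    list(a = a, b = b, r = r, tau_post = tau_post, tau_I = tau_I,
         dt = dt, horizon = horizon, cost_floor = cost_floor),
    class = "lever_task"
  )
}

#' Actor-to-critic communication regimes
#'
#' `comm_indirect()`: the critic learns of the actor's choice only via the
#' late efference copy; its expectations about the notification time are the
#' prior over `T`. `comm_direct()`: the critic additionally receives the
#' chosen latency `tau` a short delay `epsilon` after the cue, but suffers
#' scalar timing uncertainty (conditional sd `k * tau`) about when the
#' efference copy will actually arrive.
#'
#' @param epsilon Delay of the direct signal in seconds (>= 0).
#' @param k Scalar timing-noise constant (> 0).
#' @return A list of class `comm_mode`.
#' @export
comm_indirect <- function() {
  structure(list(kind = "indirect"), class = "comm_mode")
}

#' @rdname comm_indirect
#' @export
comm_direct <- function(epsilon = 0.1, k = 0.1) {
  stopifnot(epsilon >= 0, k > 0)
  structure(list(kind = "direct", epsilon = epsilon, k = k), class = "comm_mode")
}

#' Net utility of a press with notification time T
#'
#' @param spec A `lever_task`.
#' @param T Notification time(s) in seconds.
#' @return `r + a / max(T, cost_floor) + b`, vectorised.
#' @export
press_utility <- function(spec, T) {
  spec$r + spec$a / pmax(T, spec$cost_floor) + spec$b
}

#' Long-run average reward of the lever-press cycle
#'
#' Renewal-reward ratio `E[u(T)] / E[T + tau_post + tau_I]`, with the
#' expectations taken over the timing distribution by numerical integration
#' (closed form for deterministic timing). This is the opportunity cost of
#' time, the proposed correlate of tonic dopamine.
#'
#' @param spec A `lever_task`.
#' @param timing A `ramp_timing` over the notification time `T`.
#' @return Average reward rate `rho` in utility per second, with attributes
#'   `Eu` and `ET`.
#' @export
cycle_average_reward <- function(spec, timing) {
  stopifnot(inherits(spec, "lever_task"), inherits(timing, "ramp_timing"))
  if (timing$kind == "gamma" && timing$shape <= 1 && spec$cost_floor <= 0) {
    stop(paste0(
      "E[a/T] diverges for gamma timing with shape <= 1; ",
      "set a positive `cost_floor` in lever_task() to truncate the cost."
    ), call. = FALSE)
  }
  if (timing$kind == "fixed") {
    Eu <- press_utility(spec, timing$tau)
    ET <- timing$tau
  } else {
    Eu <- stats::integrate(
      function(t) press_utility(spec, t) * timing_density(timing, t),
      0, Inf, rel.tol = 1e-10, subdivisions = 500L
    )$value
    ET <- stats::integrate(
      function(t) t * timing_density(timing, t),
      0, Inf, rel.tol = 1e-10, subdivisions = 500L
    )$value
  }
  rho <- Eu / (ET + spec$tau_post + spec$tau_I)
  attr(rho, "Eu") <- Eu
  attr(rho, "ET") <- ET
  rho
}

# Backward recursion for the value deficit w(t) = V(2) - V({1, t}):
# w(t) = P(stay) * w(t + dt) + rho * dt, solved from the grid horizon where
# the deficit is taken to vanish (transition imminent). `surv` is the
# survival function of T on the grid.
solve_deficit <- function(surv, rho, dt) {
  n <- length(surv)
  w <- numeric(n)
  for (i in (n - 1L):1L) {
    p_stay <- if (surv[i] > 1e-12) min(surv[i + 1L] / surv[i], 1) else 0
    w[i] <- p_stay * w[i + 1L] + rho * dt
  }
  w
}

default_horizon <- function(spec, timing, mode) {
  if (!is.null(spec$horizon)) return(spec$horizon)
  if (mode$kind == "indirect") {
    stats::qgamma(1e-10, shape = timing$shape, scale = timing$scale,
                  lower.tail = FALSE)
  } else {
    tau_max <- stats::qgamma(1e-3, shape = timing$shape, scale = timing$scale,
                             lower.tail = FALSE)
    tau_max * (1 + 5 * mode$k) + 1
  }
}

#' Relative values of the lever-press SMDP
#'
#' Solves the microstate relative values `V({1, t})` by backward recursion of
#' the probability-weighted consistency condition
#' `V({1, t}) = P(stay) V({1, t + dt}) + P(go) V(2) - rho dt`,
#' anchored at `V(3) = 0` (relative values are defined up to an additive
#' constant; only differences enter TD errors). In the indirect regime the
#' critic's expectations over `T` are the gamma prior; in the direct regime
#' one value table is solved per latency `tau` on the grid, under the
#' truncated-Gaussian conditional timing, and the pre-signal state of
#' ignorance is valued as the policy-weighted average at the signal delay
#' `epsilon`.
#'
#' The state of preparedness carries a single, choice-independent value
#' `V(2) = E[u] - rho * tau_post + V(3)` under the policy-expected trial
#' utility; the residual utility surprise `u(T) - E[u]` is realised as a
#' prediction error at press completion.
#'
#' @param spec A `lever_task`.
#' @param timing A `timing_gamma` prior over `T` (indirect mode) or over the
#'   actor's latency choice `tau` (direct mode; the distributions of `tau`
#'   and `T` coincide apart from timing noise).
#' @param mode A `comm_mode`.
#' @return A list of class `rv_table` with elements `rho`, `Eu`, `t_grid`,
#'   `v1` (vector, or matrix with one column per `tau` in direct mode),
#'   `v2`, `v3`, `v10`, and in direct mode `tau_grid` and `p_tau`.
#' @export
solve_relative_values <- function(spec, timing, mode = comm_indirect()) {
  stopifnot(inherits(spec, "lever_task"), inherits(mode, "comm_mode"))
  dt <- spec$dt
  horizon <- default_horizon(spec, timing, mode)
  t_grid <- seq(0, horizon, by = dt)
  n <- length(t_grid)
  v3 <- 0

  if (mode$kind == "indirect") {
    rho <- cycle_average_reward(spec, timing)
    Eu <- attr(rho, "Eu")
    surv <- timing_survival(timing, t_grid)
    w <- solve_deficit(surv, as.numeric(rho), dt)
    v2 <- Eu - as.numeric(rho) * spec$tau_post + v3
    v1 <- v2 - w
    out <- list(
      spec = spec, timing = timing, mode = mode,
      rho = as.numeric(rho), Eu = Eu, ET = attr(rho, "ET"),
      t_grid = t_grid, surv = surv, v1 = v1, v2 = v2, v3 = v3, v10 = v1[1L]
    )
  } else {
    stopifnot(inherits(timing, "timing_gamma"))
    tau_max <- stats::qgamma(1e-3, shape = timing$shape, scale = timing$scale,
                             lower.tail = FALSE)
    tau_grid <- t_grid[t_grid > 0 & t_grid <= tau_max]
    p_tau <- timing_density(timing, tau_grid)
    p_tau <- p_tau / sum(p_tau * dt)
    m <- length(tau_grid)
    # conditional survival and per-tau utility/timing moments on the grid
    surv <- matrix(0, n, m)
    Eu_tau <- ET_tau <- numeric(m)
    u_grid <- press_utility(spec, t_grid)
    for (j in seq_len(m)) {
      cond <- timing_conditional(tau_grid[j], mode$k)
      surv[, j] <- timing_survival(cond, t_grid)
      dens <- timing_density(cond, t_grid)
      dens <- dens / sum(dens * dt)
      Eu_tau[j] <- sum(dens * u_grid * dt)
      ET_tau[j] <- sum(dens * t_grid * dt)
    }
    Eu <- sum(p_tau * Eu_tau * dt)
    ET <- sum(p_tau * ET_tau * dt)
    rho <- Eu / (ET + spec$tau_post + spec$tau_I)
    # vectorised backward recursion across tau columns
    W <- matrix(0, n, m)
    for (i in (n - 1L):1L) {
      p_stay <- ifelse(surv[i, ] > 1e-12, pmin(surv[i + 1L, ] / surv[i, ], 1), 0)
      W[i, ] <- p_stay * W[i + 1L, ] + rho * dt
    }
    v2 <- Eu - rho * spec$tau_post + v3
    v1 <- v2 - W
    i_eps <- round(mode$epsilon / dt) + 1L
    v10 <- -rho * mode$epsilon + sum(p_tau * v1[i_eps, ] * dt)
    out <- list(
      spec = spec, timing = timing, mode = mode,
      rho = rho, Eu = Eu, ET = ET, Eu_tau = Eu_tau,
      t_grid = t_grid, surv = surv, tau_grid = tau_grid, p_tau = p_tau,
      v1 = v1, v2 = v2, v3 = v3, v10 = v10, i_eps = i_eps
    )
  }
  class(out) <- "rv_table"
  out
}

#' Residual of the relative-value consistency condition
#'
#' Plugs the solved microstate values back into the probability-weighted
#' recursion and returns the per-gridpoint residual (excluding the horizon
#' anchor point); a correct table has residuals at numerical zero.
#'
#' @param table An `rv_table`.
#' @return Numeric vector (indirect) or matrix (direct) of residuals.
#' @export
rv_residual <- function(table) {
  dt <- table$spec$dt
  n <- length(table$t_grid)
  if (table$mode$kind == "indirect") {
    p_stay <- ifelse(table$surv[-n] > 1e-12,
                     pmin(table$surv[-1L] / table$surv[-n], 1), 0)
    table$v1[-n] -
      (p_stay * table$v1[-1L] + (1 - p_stay) * table$v2 - table$rho * dt)
  } else {
    p_stay <- ifelse(table$surv[-n, , drop = FALSE] > 1e-12,
                     pmin(table$surv[-1L, , drop = FALSE] /
                            table$surv[-n, , drop = FALSE], 1), 0)
    table$v1[-n, , drop = FALSE] -
      (p_stay * table$v1[-1L, , drop = FALSE] +
         (1 - p_stay) * table$v2 - table$rho * dt)
  }
}

#' @export
print.rv_table <- function(x, ...) {
  cat(sprintf(
    "lever-press SMDP relative values (%s mode)\n  rho = %.6g utility/s, E[u] = %.6g, grid [0, %g] s (dt = %g)\n",
    x$mode$kind, x$rho, x$Eu, max(x$t_grid), x$spec$dt
  ))
  invisible(x)
}

#' @export
tidy.rv_table <- function(x, ...) {
  if (x$mode$kind == "indirect") {
    tibble::tibble(t_hat = x$t_grid, v1 = x$v1)
  } else {
    tibble::as_tibble(expand.grid(t_hat = x$t_grid, tau = x$tau_grid)) |>
      dplyr::mutate(v1 = as.vector(x$v1))
  }
}

#' @export
glance.rv_table <- function(x, ...) {
  tibble::tibble(
    mode = x$mode$kind, rho = x$rho, Eu = x$Eu, ET = x$ET,
    v2 = x$v2, v3 = x$v3, v10 = x$v10,
    horizon = max(x$t_grid), dt = x$spec$dt
  )
}

snap_index <- function(t, grid) {
  i <- round((t - grid[1L]) / (grid[2L] - grid[1L])) + 1L
  as.integer(pmin(pmax(i, 1L), length(grid)))
}

#' Single-trial phasic TD-error trace
#'
#' Assembles the phasic component of the TD error for one trial: an impulse
#' at cue onset (entry into the trial from the inter-trial state), the
#' waiting-period value drift while no notification arrives, the direct
#' signal at `epsilon` (direct mode only: the surprise of learning the
#' chosen latency), the efference-copy transient at `T`, and the reward-time
#' transient at press completion carrying the utility surprise. The tonic
#' term `-rho` is excluded throughout. Transients are represented as
#' impulses of height `area / dt`, so convolution amplitudes are
#' grid-invariant.
#'
#' @param table An `rv_table`.
#' @param T Notification (efference-copy) time in seconds; must lie within
#'   the grid.
#' @param tau Chosen latency in seconds (required in direct mode).
#' @param pre Seconds of pre-cue baseline included in the trace.
#' @param post Seconds of trace retained after press completion.
#' @return A list of class `trial_trace`: `delta_p` (a `ramp_ts`), `events`
#'   (tibble of event, time and impulse area), `press_time_s`, and
#'   `latency_class` (`"short"` if the press occurs before 5 s).
#' @export
td_trace <- function(table, T, tau = NULL, pre = 2, post = 4) {
  stopifnot(inherits(table, "rv_table"))
  spec <- table$spec
  dt <- spec$dt
  if (T > max(table$t_grid) || T <= 0) {
    stop("`T` must lie inside the microstate grid (0, horizon].", call. = FALSE)
  }
  direct <- table$mode$kind == "direct"
  if (direct && is.null(tau)) stop("`tau` is required in direct mode.", call. = FALSE)

  iT <- snap_index(T, table$t_grid)
  T_snap <- table$t_grid[iT]
  press_t <- T_snap + spec$tau_post
  n_pre <- round(pre / dt)
  len <- n_pre + round((press_t + post) / dt) + 1L
  val <- numeric(len)
  at <- function(t) n_pre + round(t / dt) + 1L

  if (direct) {
    j <- snap_index(tau, table$tau_grid)
    v1 <- table$v1[, j]
    eps <- table$mode$epsilon
    i_eps <- table$i_eps
    cue_area <- table$v10 - table$v3
    sig_area <- v1[i_eps] - (table$v10 + table$rho * eps)
    i_wait <- seq(i_eps, iT - 1L)
  } else {
    v1 <- table$v1
    cue_area <- v1[1L] - table$v3
    sig_area <- NULL
    i_wait <- seq(1L, iT - 1L)
  }
  events <- tibble::tibble(
    event = "cue", time_s = 0, area = cue_area
  )
  val[at(0)] <- val[at(0)] + cue_area / dt
  if (direct && iT > table$i_eps) {
    val[at(table$mode$epsilon)] <- val[at(table$mode$epsilon)] + sig_area / dt
    events <- dplyr::bind_rows(events, tibble::tibble(
      event = "direct_signal", time_s = table$mode$epsilon, area = sig_area
    ))
  }
  # waiting-period drift: realised per-second change of V({1, t}) while no
  # notification arrives
  if (length(i_wait) > 0 && iT > i_wait[1L]) {
    drift <- (v1[i_wait + 1L] - v1[i_wait]) / dt
    idx <- n_pre + i_wait
    val[idx] <- val[idx] + drift
  }
  eff_area <- table$v2 - v1[iT]
  val[at(T_snap)] <- val[at(T_snap)] + eff_area / dt
  press_area <- press_utility(spec, T_snap) - table$Eu + table$rho * spec$tau_post
  val[at(press_t)] <- val[at(press_t)] + press_area / dt
  events <- dplyr::bind_rows(
    events,
    tibble::tibble(event = "efference_copy", time_s = T_snap, area = eff_area),
    tibble::tibble(event = "press", time_s = press_t, area = press_area)
  )
  structure(
    list(
      delta_p = ramp_ts(val, dt = dt, t0 = -n_pre * dt),
      events = events,
      T = T_snap, tau = tau, press_time_s = press_t,
      latency_class = if (press_t < 5) "short" else "long"
    ),
    class = "trial_trace"
  )
}

#' Simulate a session of cued lever presses
#'
#' Draws `n` trials, assembles each trial's phasic TD-error trace, applies
#' the asymmetric scaling of negative errors, convolves with the dopamine
#' response kernel, and returns event-aligned averages together with
#' per-trial peak summaries. Trials are classed as short or long latency at
#' a press time of 5 s. Peak windows are shifted by the kernel time constant
#' `xi` (the response to an event peaks `xi` seconds after it): the cue
#' window spans `[0, 5 + xi)` and the press window `press + xi ± 2.5` s.
#'
#' @param table An `rv_table` (its mode determines the trial generator: in
#'   direct mode the latency `tau` is drawn from the gamma policy and `T`
#'   from the conditional timing; in indirect mode `T` is drawn from the
#'   prior).
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @param d Asymmetric scaling of negative errors in (0, 1].
#' @param kernel A `drf_kernel` on the task's grid step.
#' @return A list of class `lever_session`: `cue_aligned`,
#'   `press_aligned_short`, `press_aligned_long` (each an `aligned_avg`),
#'   `peak_summary` (tibble: latency_class, window, mean, sem, n), and
#'   `trials` (per-trial tibble).
#' @export
simulate_lever_session <- function(table, n = 1000, seed = 1, d = 1 / 6,
                                   kernel = drf_kernel(dt = table$spec$dt)) {
  stopifnot(inherits(table, "rv_table"), n >= 1)
  spec <- table$spec
  dt <- spec$dt
  xi <- attr(kernel, "xi")
  set.seed(seed)
  direct <- table$mode$kind == "direct"
  t_max <- max(table$t_grid)

  traces <- vector("list", n)
  trials <- tibble::tibble(
    trial = seq_len(n), tau = NA_real_, T = NA_real_,
    press_time_s = NA_real_, latency_class = NA_character_,
    peak_cue = NA_real_, peak_press = NA_real_
  )
  for (i in seq_len(n)) {
    if (direct) {
      tau <- sample_timing(table$timing, 1L)
      tau <- min(max(tau, dt), max(table$tau_grid))
      T <- sample_timing(timing_conditional(tau, table$mode$k), 1L)
      T <- min(max(T, dt), t_max)
    } else {
      tau <- NA_real_
      T <- sample_timing(table$timing, 1L)
      T <- min(max(T, dt), t_max)
    }
    # keep every trace long enough to cover both the cue window and the
    # cue-aligned averaging window, even for very short presses
    post_i <- max(4, 6 + xi - (T + spec$tau_post))
    tr <- td_trace(table, T = T, tau = if (direct) tau else NULL,
                   pre = 2, post = post_i)
    da <- convolve_drf(rectify_errors(tr$delta_p, d), kernel)
    tt <- da$time_s
    cue_win <- tt >= 0 & tt < 5 + xi
    press_win <- tt >= tr$press_time_s - 2.5 + xi &
      tt <= tr$press_time_s + 2.5 + xi
    trials$tau[i] <- tau
    trials$T[i] <- tr$T
    trials$press_time_s[i] <- tr$press_time_s
    trials$latency_class[i] <- tr$latency_class
    trials$peak_cue[i] <- max(da$value[cue_win])
    trials$peak_press[i] <- max(da$value[press_win])
    traces[[i]] <- da
  }

  short <- trials$latency_class == "short"
  cue_aligned <- aligned_average(traces, rep(0, n), window = c(2, 5))
  aa_or_null <- function(keep, align, window) {
    if (!any(keep)) return(NULL)
    aligned_average(traces[keep], align[keep], window = window)
  }
  press_aligned_short <- aa_or_null(short, trials$press_time_s, c(2.5, 3))
  press_aligned_long <- aa_or_null(!short, trials$press_time_s, c(2.5, 3))

  peak_summary <- trials |>
    tidyr::pivot_longer(c("peak_cue", "peak_press"),
                        names_to = "window", values_to = "peak") |>
    dplyr::mutate(window = sub("^peak_", "", .data$window)) |>
    dplyr::group_by(.data$latency_class, .data$window) |>
    dplyr::summarise(
      mean = mean(.data$peak),
      sem = stats::sd(.data$peak) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )

  structure(
    list(
      cue_aligned = cue_aligned,
      press_aligned_short = press_aligned_short,
      press_aligned_long = press_aligned_long,
      peak_summary = peak_summary,
      trials = trials,
      seed = seed, d = d
    ),
    class = "lever_session"
  )
}

#' @export
tidy.lever_session <- function(x, ...) x$trials

#' @export
glance.lever_session <- function(x, ...) {
  x$peak_summary |>
    tidyr::pivot_wider(names_from = "window", values_from = c("mean", "sem")) |>
    dplyr::rename(n_trials = "n")
}
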