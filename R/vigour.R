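#' Discounted latency-choice problems
#'
#' In the discounted-reward setting, the role of the opportunity cost
#' `-rho * tau` is played by the decay of future value, `gamma^tau`. A
#' `vigour_problem` couples the hyperbolic vigour cost `a / tau` with a
#' per-second exponential discount `gamma`. Two chain structures are
#' supported: `terminating`, where the post-action value is fixed at 1
#' regardless of `tau` and `gamma` (a single shot at a goal), and
#' `continuing`, where completing the press is followed, after an interval
#' `tau_I`, by a further opportunity to press.
#'
#' @param a Hyperbolic cost factor in utility-seconds (<= 0).
#' @param gamma Per-second discount factor in (0, 1).
#' @param r Reward utility (> 0; used by the continuing chain).
#' @param chain `"terminating"` or `"continuing"`.
#' @param tau_I Inter-trial interval in seconds (continuing chain).
#' @return A list of class `vigour_problem`.
#' @export
vigour_problem <- function(a, gamma, r = 1,
                           chain = c("terminating", "continuing"),
                           tau_I = 30) {
  chain <- match.arg(chain)
  stopifnot(a <= 0, gamma > 0, gamma < 1, r > 0, tau_I >= 0)
  structure(list(a = a, gamma = gamma, r = r, chain = chain, tau_I = tau_I),
            class = "vigour_problem")
}

#' Discounted action value of a latency
#'
#' `Q(tau) = a / tau + gamma^tau * v_next`: the cost of acting with latency
#' `tau` plus the discounted value of the post-action state. In the
#' terminating convention the immediate reward is folded into `v_next = 1`.
#'
#' @param p A `vigour_problem`.
#' @param tau Latency in seconds (> 0); vectorised.
#' @param v_next Value of the post-action state.
#' @return Numeric vector of utilities.
#' @export
q_gamma <- function(p, tau, v_next = 1) {
  stopifnot(inherits(p, "vigour_problem"))
  if (any(tau <= 0)) stop("`tau` must be positive.", call. = FALSE)
  p$a / tau + p$gamma^tau * v_next
}

#' Analytic bound on the cost of acting
#'
#' For the terminating problem there is a limiting cost
#' `a_min = 4 / (e^2 * log(gamma))` (a negative number) below which no
#' optimal latency exists: acting quickly is so expensive that the implied
#' latency discounts the unit future value below the cost of attaining it.
#' It follows from maximising `tau^2 * gamma^tau * |log gamma|`, the
#' stationarity condition of `Q`, over `tau`.
#'
#' @param gamma Per-second discount factor in (0, 1).
#' @return The bound in utility-seconds (negative).
#' @examples
#' a_min(0.98) # about -26.80
#' @export
a_min <- function(gamma) {
  if (any(gamma >= 1) || any(gamma <= 0)) {
    stop("`gamma` must lie strictly in (0, 1).", call. = FALSE)
  }
  4 / (exp(2) * log(gamma))
}

# interior maximiser of a / tau + gamma^tau * v_next, or NA when the cost
# exceeds the bound. Coarse log-grid bracket refined by golden-section
# (stats::optimize); ties broken toward the smaller root by restricting the
# search to (0, 2 / |log gamma|], where the first stationary point lies.
tau_star_core <- function(a, gamma, v_next = 1, tol = 1e-4) {
  if (v_next <= 0) return(NA_real_)
  if (a / v_next < a_min(gamma)) return(NA_real_)
  tau_peak <- 2 / abs(log(gamma))
  grid <- exp(seq(log(1e-4), log(tau_peak), length.out = 1000L))
  qv <- a / grid + gamma^grid * v_next
  i <- which.max(qv)
  lo <- grid[max(i - 1L, 1L)]
  hi <- if (i == length(grid)) tau_peak else grid[i + 1L]
  opt <- stats::optimize(function(t) a / t + gamma^t * v_next,
                         lower = lo, upper = hi, maximum = TRUE, tol = tol)
  opt$maximum
}

#' Optimal press latency under discounting
#'
#' For a terminating problem, maximises `Q(tau) = a / tau + gamma^tau`. For
#' a continuing problem the post-action value is itself part of the
#' solution: `V = max_tau [a / tau + gamma^tau * (r + gamma^tau_I * V)]` is
#' solved by damped fixed-point iteration, and the optimal latency reported
#' at the fixed point. Returns `NA` (no solution) when the cost of acting
#' lies below the analytic bound.
#'
#' @param p A `vigour_problem`.
#' @param tol Refinement tolerance on `tau` in seconds.
#' @return A list of class `optimal_latency`: `tau_star` (seconds or `NA`),
#'   `value` (the attained `Q`/fixed-point value), `v_next`, `converged`,
#'   `residual` (continuing chain).
#' @export
optimal_latency <- function(p, tol = 1e-4) {
  stopifnot(inherits(p, "vigour_problem"))
  if (p$chain == "terminating") {
    ts <- tau_star_core(p$a, p$gamma, v_next = 1, tol = tol)
    val <- if (is.na(ts)) NA_real_ else q_gamma(p, ts, v_next = 1)
    return(structure(
      list(tau_star = ts, value = val, v_next = 1, converged = TRUE,
           residual = 0, problem = p),
      class = "optimal_latency"
    ))
  }
  V <- 0
  converged <- FALSE
  for (i in seq_len(5000L)) {
    v_next <- p$r + p$gamma^p$tau_I * V
    ts <- tau_star_core(p$a, p$gamma, v_next = v_next, tol = tol / 10)
    if (is.na(ts)) {
      return(structure(
        list(tau_star = NA_real_, value = NA_real_, v_next = v_next,
             converged = FALSE, residual = NA_real_, problem = p),
        class = "optimal_latency"
      ))
    }
    V_new <- p$a / ts + p$gamma^ts * v_next
    V_next <- 0.5 * V + 0.5 * V_new
    if (abs(V_next - V) < 1e-12) {
      V <- V_next
      converged <- TRUE
      break
    }
    V <- V_next
  }
  v_next <- p$r + p$gamma^p$tau_I * V
  ts <- tau_star_core(p$a, p$gamma, v_next = v_next, tol = tol)
  structure(
    list(
      tau_star = ts, value = V, v_next = v_next, converged = converged,
      residual = abs(V - (p$a / ts + p$gamma^ts * v_next)), problem = p
    ),
    class = "optimal_latency"
  )
}

#' @export
print.optimal_latency <- function(x, ...) {
  if (is.na(x$tau_star)) {
    cat("no optimal latency: cost of acting below the a_min bound\n")
  } else {
    cat(sprintf("tau* = %.4f s (value %.6g, %s chain)\n",
                x$tau_star, x$value, x$problem$chain))
  }
  invisible(x)
}

#' Continuing-minus-terminating shift in optimal latency
#'
#' When the inter-trial interval is long relative to `-1 / log(gamma)`, the
#' prospect of future trials is discounted away and the continuing optimal
#' latency is essentially the terminating one; when it is short, future
#' rewards hasten pressing and the difference turns negative.
#'
#' @param a Cost factor (<= 0).
#' @param gamma Per-second discount in (0, 1).
#' @param tau_I Inter-trial interval in seconds.
#' @param r Reward utility.
#' @return A tibble with `tau_star_terminating`, `tau_star_continuing`,
#'   `delta_tau_star`, and a `reason` column (`NA` unless one side has no
#'   solution).
#' @export
delta_tau_star <- function(a, gamma, tau_I, r = 1) {
  term <- optimal_latency(vigour_problem(a, gamma, r, "terminating"))
  cont <- optimal_latency(vigour_problem(a, gamma, r, "continuing", tau_I))
  reason <- NA_character_
  if (is.na(term$tau_star)) reason <- "terminating problem has no solution"
  if (is.na(cont$tau_star)) reason <- "continuing problem has no solution"
  tibble::tibble(
    a = a, gamma = gamma, tau_I = tau_I, r = r,
    tau_star_terminating = term$tau_star,
    tau_star_continuing = cont$tau_star,
    delta_tau_star = cont$tau_star - term$tau_star,
    reason = reason
  )
}

#' Synthetic goal-approach trajectories
#'
#' Generates proximity-to-goal profiles emulating maze runs: `"monotone"`
#' approaches the goal at unit speed (proximity is remaining time-to-goal,
#' so it falls 1 s per second), while `"pause_retreat"` inserts a stationary
#' pause and a retreat segment before resuming, giving a non-monotone
#' approach.
#'
#' @param duration Approach duration in seconds (time to goal at the start).
#' @param r Reward utility at the goal.
#' @param dt Grid step in seconds.
#' @param type `"monotone"` or `"pause_retreat"`.
#' @param post Seconds dwelling at the goal after arrival.
#' @param pause_at,pause_len Start and length of the stationary pause
#'   (pause-retreat type), seconds.
#' @param retreat_len,retreat_speed Length (s) and speed (proximity gained
#'   per second) of the retreat segment.
#' @return A tibble of class `ramp_trajectory` with columns `time_s`,
#'   `proximity`, and attribute `r`.
#' @export
synth_trajectory <- function(duration = 10, r = 1, dt = 0.01,
                             type = c("monotone", "pause_retreat"),
                             post = 1,
                             pause_at = 0.4 * duration, pause_len = 2,
                             retreat_len = 1.5, retreat_speed = 1) {
  type <- match.arg(type)
  stopifnot(duration > 0, r > 0, dt > 0)
  if (type == "monotone") {
    tt <- seq(0, duration + post, by = dt)
    prox <- pmax(duration - tt, 0)
  } else {
    p <- duration
    prox <- p
    repeat {
      t_now <- (length(prox) - 1L) * dt
      if (t_now < pause_at || t_now >= pause_at + pause_len + retreat_len) {
        p <- max(p - dt, 0)
      } else if (t_now < pause_at + pause_len) {
        # stationary pause: proximity unchanged
      } else {
        p <- p + retreat_speed * dt
      }
      prox <- c(prox, p)
      if (p == 0) break
    }
    prox <- c(prox, rep(0, round(post / dt)))
    tt <- dt * (seq_along(prox) - 1L)
  }
  out <- tibble::tibble(time_s = tt, proximity = prox)
  attr(out, "r") <- r
  class(out) <- c("ramp_trajectory", class(out))
  out
}

#' Quasi-tonic value signal over a goal-approach trajectory
#'
#' The discounted state value along the trajectory is `V(t) =
#' gamma^proximity(t) * r` (proximity in seconds of remaining travel; the
#' goal reward is encoded as the goal-state value, so no separate reward
#' stream appears). The quasi-tonic signal is `(1 - gamma) * V(s_[t+1])`,
#' with the successor state taken one second ahead on the grid — the
#' bookkeeping step at which `gamma` is the per-step discount. The
#' undiscounted phasic error is `delta_A(t) = V(s_[t+1]) - V(s_t)`. Both are
#' reported where the one-second lookahead stays inside the trajectory;
#' the modelled concentration `da` is the quasi-tonic signal convolved with
#' the response kernel.
#'
#' @param traj A `ramp_trajectory` (columns `time_s`, `proximity`;
#'   proximity must be non-negative).
#' @param gamma Per-second discount in (0, 1).
#' @param kernel A `drf_kernel` on the trajectory's grid step.
#' @param r Reward utility at the goal; defaults to the trajectory's own.
#' @return A tibble of class `ramp_result` with columns `time_s`,
#'   `quasi_tonic`, `delta_A`, `da`, and attributes `gamma`, `r`.
#' @export
quasi_tonic_trace <- function(traj, gamma, kernel = NULL, r = NULL) {
  stopifnot(inherits(traj, "ramp_trajectory") || is.data.frame(traj))
  if (any(traj$proximity < 0)) {
    stop("`proximity` must be non-negative.", call. = FALSE)
  }
  stopifnot(gamma > 0, gamma < 1)
  r <- r %||% attr(traj, "r") %||% 1
  dt <- (traj$time_s[nrow(traj)] - traj$time_s[1L]) / (nrow(traj) - 1L)
  if (is.null(kernel)) kernel <- drf_kernel(dt = dt)
  n <- nrow(traj)
  step <- round(1 / dt)
  if (n <= step) stop("trajectory shorter than the one-second value step.",
                      call. = FALSE)
  V <- gamma^traj$proximity * r
  keep <- seq_len(n - step)
  v_next <- V[keep + step]
  qt <- (1 - gamma) * v_next
  dA <- v_next - V[keep]
  # concentration is proportional to the convolution; normalising by the
  # kernel area keeps a sustained signal at its own scale, so `da` is a
  # smoothed, delayed copy of the quasi-tonic trace
  k_area <- sum(kernel$value) * attr(kernel, "dt")
  da <- convolve_drf(ramp_ts(qt, dt = dt, t0 = traj$time_s[1L]), kernel)$value / k_area
  out <- tibble::tibble(
    time_s = traj$time_s[keep],
    quasi_tonic = qt, delta_A = dA, da = da
  )
  attr(out, "gamma") <- gamma
  attr(out, "r") <- r
  class(out) <- c("ramp_result", class(out))
  out
}

#' @export
autoplot.ramp_result <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("quasi_tonic", "delta_A", "da"),
                              names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Discounted values of a deterministic reward cycle
#'
#' For an ergodic cyclic chain with one fixed reward per state and
#' deterministic unit-time transitions, solves the discounted values
#' `V(s) = r(s) + gamma * V(next(s))` exactly and reports the gap between
#' the scaled values `(1 - gamma) * V(s)` and the cycle-average reward
#' `rho = mean(rewards)`. The gap vanishes as `gamma` approaches 1 — the
#' formal continuity between the discounted and average-reward accounts.
#'
#' @param rewards Numeric vector of per-state rewards (cycle order).
#' @param gamma Discount factor in (0, 1).
#' @return A tibble with columns `state`, `reward`, `v`, `scaled_v`, and
#'   attributes `rho` and `gap` (`max |scaled_v - rho|`).
#' @export
cycle_chain_values <- function(rewards, gamma) {
  stopifnot(length(rewards) >= 1L, gamma > 0, gamma < 1)
  k <- length(rewards)
  # V_i = sum_{j=0}^{k-1} gamma^j r_{i+j} / (1 - gamma^k), indices mod k
  V <- vapply(seq_len(k), function(i) {
    idx <- ((i - 1L + seq_len(k) - 1L) %% k) + 1L
    sum(gamma^(seq_len(k) - 1L) * rewards[idx]) / (1 - gamma^k)
  }, numeric(1))
  rho <- mean(rewards)
  out <- tibble::tibble(
    state = seq_len(k), reward = rewards, v = V, scaled_v = (1 - gamma) * V
  )
  attr(out, "rho") <- rho
  attr(out, "gap") <- max(abs(out$scaled_v - rho))
  out
}
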