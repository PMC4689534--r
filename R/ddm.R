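#' Parameter objects for the gain-modulated decision process
#'
#' `ou_params()` describes the tonic dopamine fluctuations: a discrete-time
#' Ornstein-Uhlenbeck (AR(1)) process updated once per grid step of length
#' `dt`, `g[k+1] = g[k] + kappa * (theta - g[k]) + sigma * e[k]`, with
#' `e[k] ~ N(0, 1)`. `kappa` and `sigma` are per-step quantities; the
#' stationary variance is `sigma^2 / (2 * kappa - kappa^2)`, approximately
#' `sigma^2 / (2 * kappa)` for small `kappa`, and the correlation time is
#' `dt / kappa` seconds.
#'
#' `ddm_params()` describes the drift-diffusion core, `dx = g(t) * (A dt +
#' c dW)`: drift `A` (the value difference between the two options), white
#' noise of intensity `c` on the continuous-time scale, and a symmetric
#' threshold at `±z`.
#'
#' `phasic_spec()` describes an optional phasic dopamine event: a TD
#' response of random magnitude `h ~ N(mu, sd^2)` occurring `time` seconds
#' into the trial, converted to a gain transient by the alpha-function
#' response kernel (the transient peaks at `h` above the tonic level, `xi`
#' seconds after the event).
#'
#' @param theta Long-term mean gain (> 0).
#' @param kappa Per-step mean-reversion rate (in [0, 1]).
#' @param sigma Per-step noise standard deviation (>= 0).
#' @param dt Grid step in seconds (> 0).
#' @param A Drift in evidence per second.
#' @param c Diffusion intensity in evidence per root-second (>= 0).
#' @param z Threshold in evidence units (> 0).
#' @param mu,sd Mean and standard deviation of the phasic magnitude `h`.
#' @param time Onset of the phasic event in seconds from trial start.
#' @param xi Response-kernel time constant in seconds.
#' @return A parameter list of class `ou_params`, `ddm_params`, or
#'   `phasic_spec` respectively.
#' @name gain_ddm_params
NULL

#' @rdname gain_ddm_params
#' @export
ou_params <- function(theta = 1, kappa = 0.01, sigma = 0.1, dt = 0.01) {
  stopifnot(theta > 0, kappa >= 0, kappa <= 1, sigma >= 0, dt > 0)
  structure(list(theta = theta, kappa = kappa, sigma = sigma, dt = dt),
            class = "ou_params")
}

#' @rdname gain_ddm_params
#' @export
ddm_params <- function(A = 1, c = 1, z = 5) {
  stopifnot(c >= 0, z > 0)
  structure(list(A = A, c = c, z = z), class = "ddm_params")
}

#' @rdname gain_ddm_params
#' @export
phasic_spec <- function(mu = 4, sd = 1, time = 1, xi = 0.7) {
  stopifnot(sd >= 0, time >= 0, xi > 0)
  structure(list(mu = mu, sd = sd, time = time, xi = xi),
            class = "phasic_spec")
}

ou_path <- function(p, n_steps, innovations = NULL) {
  if (p$sigma == 0) return(rep(p$theta, n_steps)) # theta is a fixed point
  if (is.null(innovations)) innovations <- stats::rnorm(n_steps - 1L)
  g <- numeric(n_steps)
  g[1L] <- p$theta
  for (k in seq_len(n_steps - 1L)) {
    g[k + 1L] <- g[k] + p$kappa * (p$theta - g[k]) + p$sigma * innovations[k]
  }
  g
}

# First passage of the sampled path through ±z, including Brownian-bridge
# crossings between samples (without the bridge test the discrete scheme
# systematically misses intra-step excursions, biasing latencies upward by
# ~0.5826 * c * sqrt(dt) in threshold units). `u` is one uniform per step.
first_crossing <- function(x, g, c, z, dt, u) {
  hit <- which(abs(x) >= z)
  i_hit <- if (length(hit)) hit[1L] else Inf
  n <- length(x)
  x0 <- c(0, x[-n])
  denom <- (c * g)^2 * dt
  p_up <- exp(-2 * (z - x0) * (z - x) / denom)
  p_lo <- exp(-2 * (z + x0) * (z + x) / denom)
  inside <- seq_len(n) < i_hit
  br <- which(inside & u < pmin(p_up + p_lo, 1))
  i_br <- if (length(br)) br[1L] else Inf
  if (!is.finite(i_hit) && !is.finite(i_br)) return(NULL)
  if (i_br < i_hit) {
    j <- i_br
    sgn <- if (u[j] < p_up[j]) 1 else -1
    time <- (j - 0.5) * dt
  } else {
    j <- i_hit
    x_prev <- if (j == 1L) 0 else x[j - 1L]
    frac <- (z * sign(x[j]) - x_prev) / (x[j] - x_prev)
    time <- (j - 1L + frac) * dt
    sgn <- sign(x[j])
  }
  list(index = j, time = time, sign = sgn)
}

#' Simulate tonic gain fluctuations
#'
#' @param p An `ou_params`.
#' @param duration Path length in seconds (> 0).
#' @param seed Optional integer seed.
#' @return A `ramp_ts` starting at `g(0) = theta`.
#' @export
simulate_ou <- function(p, duration, seed = NULL) {
  stopifnot(inherits(p, "ou_params"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / p$dt) + 1L
  ramp_ts(ou_path(p, n), dt = p$dt)
}

phasic_transient <- function(phasic, h, n_steps, dt) {
  out <- numeric(n_steps)
  if (is.null(phasic)) return(out)
  ker <- drf_kernel(xi = phasic$xi, dt = dt)$value
  i0 <- round(phasic$time / dt)
  m <- min(n_steps - i0, length(ker))
  if (m > 0) out[i0 + seq_len(m)] <- h * ker[seq_len(m)]
  out
}

#' Simulate one gain-modulated decision trial
#'
#' Integrates `dx = g(t) * (A dt + c sqrt(dt) e)` with `x(0) = 0` until the
#' first crossing of `±z` or `max_duration`. The gain is the tonic OU path
#' plus, optionally, a phasic transient of magnitude `h ~ N(mu, sd^2)`,
#' floored at `1e-6` (a concentration cannot be negative; a negative gain
#' would invert the evidence). The crossing time is refined below the grid
#' step by linear interpolation of the final increment.
#'
#' @param ou An `ou_params`.
#' @param ddm A `ddm_params`.
#' @param phasic A `phasic_spec`, or `NULL` for tonic-only trials.
#' @param seed Optional integer seed.
#' @param max_duration Censoring horizon in seconds.
#' @param gain_floor Lower bound applied to the gain.
#' @return A list of class `decision_trial`: `x_path` and `g_path`
#'   (`ramp_ts`, truncated at the crossing step), `crossing_time` (seconds,
#'   or `NA` if censored), `sign` (±1 or `NA`), `h` (phasic magnitude or
#'   `NA`), and `n_floored` (gain samples clipped at the floor).
#' @export
simulate_trial <- function(ou, ddm, phasic = NULL, seed = NULL,
                           max_duration = 60, gain_floor = 1e-6) {
  stopifnot(inherits(ou, "ou_params"), inherits(ddm, "ddm_params"))
  if (!is.null(seed)) set.seed(seed)
  dt <- ou$dt
  n <- round(max_duration / dt)
  h <- if (is.null(phasic)) NA_real_ else stats::rnorm(1L, phasic$mu, phasic$sd)
  g <- ou_path(ou, n)
  g <- g + phasic_transient(phasic, h, n, dt)
  n_floored <- sum(g < gain_floor)
  g <- pmax(g, gain_floor)
  x <- cumsum(g * (ddm$A * dt + ddm$c * sqrt(dt) * stats::rnorm(n)))
  fc <- first_crossing(x, g, ddm$c, ddm$z, dt, stats::runif(n))
  if (is.null(fc)) {
    crossing <- NA_real_
    sgn <- NA_real_
    keep <- n
  } else {
    crossing <- fc$time
    sgn <- fc$sign
    x[fc$index] <- ddm$z * sgn
    keep <- fc$index
  }
  structure(
    list(
      x_path = ramp_ts(c(0, x[seq_len(keep)]), dt = dt),
      g_path = ramp_ts(g[seq_len(keep)], dt = dt),
      crossing_time = crossing, sign = sgn, h = h, n_floored = n_floored
    ),
    class = "decision_trial"
  )
}

#' Ensemble of gain-modulated decision trials
#'
#' Runs `n` trials, aligns the gain (modelled dopamine concentration) to the
#' time of threshold crossing, and, when phasic events are present, reports
#' the Pearson correlation between the phasic magnitude `h` and the crossing
#' latency. Non-crossing trials are excluded from the aligned average and
#' the correlation, with their count reported.
#'
#' @param ou An `ou_params`.
#' @param ddm A `ddm_params`.
#' @param phasic A `phasic_spec`, or `NULL`.
#' @param n Number of trials (>= 2).
#' @param seed Integer seed.
#' @param window Length-2 `c(pre, post)` seconds for the crossing-aligned
#'   average of the gain.
#' @param max_duration Censoring horizon in seconds.
#' @return A list of class `ddm_ensemble`: `trials` (tibble with columns
#'   `trial`, `h`, `crossing_time_s`, `sign`, `crossed`), `aligned`
#'   (crossing-aligned `aligned_avg` of the gain), `corr` (or `NA` when
#'   fewer than 2 crossing trials or no phasic events), `n_censored`,
#'   `n_floored`.
#' @export
run_ensemble <- function(ou, ddm, phasic = NULL, n = 1000, seed = 1,
                         window = c(2, 0), max_duration = 60) {
  stopifnot(n >= 2)
  set.seed(seed)
  dt <- ou$dt
  n_steps <- round(max_duration / dt)
  has_phasic <- !is.null(phasic)
  ker <- if (has_phasic) drf_kernel(xi = phasic$xi, dt = dt)$value else NULL

  hs <- lat <- sgn <- rep(NA_real_, n)
  g_paths <- vector("list", n)
  n_floored <- 0L
  for (i in seq_len(n)) {
    h <- if (has_phasic) stats::rnorm(1L, phasic$mu, phasic$sd) else NA_real_
    g <- ou_path(ou, n_steps)
    if (has_phasic) {
      i0 <- round(phasic$time / dt)
      m <- min(n_steps - i0, length(ker))
      if (m > 0) g[i0 + seq_len(m)] <- g[i0 + seq_len(m)] + h * ker[seq_len(m)]
    }
    n_floored <- n_floored + sum(g < 1e-6)
    g <- pmax(g, 1e-6)
    x <- cumsum(g * (ddm$A * dt + ddm$c * sqrt(dt) * stats::rnorm(n_steps)))
    fc <- first_crossing(x, g, ddm$c, ddm$z, dt, stats::runif(n_steps))
    if (!is.null(fc)) {
      lat[i] <- fc$time
      sgn[i] <- fc$sign
      # keep the gain only as far as alignment can use it
      g_paths[[i]] <- g[seq_len(min(fc$index + round(window[2L] / dt) + 1L,
                                    n_steps))]
    }
    hs[i] <- h
  }
  crossed <- !is.na(lat)
  trials <- tibble::tibble(
    trial = seq_len(n), h = hs, crossing_time_s = lat, sign = sgn,
    crossed = crossed
  )
  aligned <- NULL
  if (any(crossed)) {
    traces <- purrr::map(g_paths[crossed], ~ ramp_ts(.x, dt = dt))
    # a pre-crossing window longer than most latencies would exclude those
    # trials outright; shrink it to what the ensemble can support
    pre_eff <- min(window[1L],
                   floor(stats::quantile(lat[crossed], 0.25) / dt) * dt)
    aligned <- suppressWarnings(
      aligned_average(traces, lat[crossed], window = c(pre_eff, window[2L]))
    )
  }
  corr <- NA_real_
  if (has_phasic && sum(crossed) >= 2L) {
    corr <- stats::cor(hs[crossed], lat[crossed])
  }
  structure(
    list(
      trials = trials, aligned = aligned, corr = corr,
      n_censored = sum(!crossed), n_floored = n_floored,
      ou = ou, ddm = ddm, phasic = phasic, seed = seed
    ),
    class = "ddm_ensemble"
  )
}

#' @export
tidy.ddm_ensemble <- function(x, ...) x$trials

#' @export
glance.ddm_ensemble <- function(x, ...) {
  ok <- x$trials$crossed
  tibble::tibble(
    n = nrow(x$trials),
    n_crossed = sum(ok),
    n_censored = x$n_censored,
    mean_latency_s = mean(x$trials$crossing_time_s[ok]),
    median_latency_s = stats::median(x$trials$crossing_time_s[ok]),
    error_rate = mean(x$trials$sign[ok] != sign(x$ddm$A)),
    corr_h_latency = x$corr
  )
}

#' @export
autoplot.ddm_ensemble <- function(object, ...) {
  ok <- object$trials$crossed & !is.na(object$trials$h)
  if (any(ok)) {
    ggplot2::ggplot(object$trials[ok, ],
                    ggplot2::aes(x = .data$crossing_time_s, y = .data$h)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::labs(x = "latency (s)", y = "phasic magnitude h")
  } else {
    autoplot.aligned_avg(object$aligned)
  }
}
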