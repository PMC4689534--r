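#' Distributions over the efference-copy time
#'
#' The critic's expectations about when it will be notified of an impending
#' action are summarised by a distribution over the notification time `T`.
#' Two families are supported:
#'
#' * `timing_gamma(shape, scale)` — a gamma prior `G(k, theta)` over `T`,
#'   used when the critic has only indirect information about the actor's
#'   choice. `G(1, 1)` has a constant hazard; other shapes give time-varying
#'   hazards.
#' * `timing_conditional(tau, k)` — scalar-timing uncertainty about a known
#'   latency choice `tau`: Gaussian with standard deviation `k * tau`,
#'   truncated to `T > 0` and renormalised (the untruncated Gaussian puts
#'   mass on negative times, which are not realisable waits).
#' * `timing_fixed(tau)` — a degenerate (deterministic) time, convenient for
#'   closed-form checks.
#'
#' @param shape,scale Gamma shape (dimensionless) and scale (seconds), both > 0.
#' @param tau Chosen latency in seconds (> 0).
#' @param k Scalar timing-noise constant (>= 0); the conditional standard
#'   deviation is `k * tau`.
#' @return An object of class `ramp_timing`.
#' @examples
#' hazard(timing_gamma(1, 1), 2.5) # exponential: constant hazard 1
#' hazard(timing_gamma(2, 1), 1)   # t / (1 + t) = 0.5
#' @name ramp_timing
NULL

#' @rdname ramp_timing
#' @export
timing_gamma <- function(shape, scale = 1) {
  stopifnot(is.numeric(shape), shape > 0, is.numeric(scale), scale > 0)
  structure(
    list(kind = "gamma", shape = shape, scale = scale),
    class = c("timing_gamma", "ramp_timing")
  )
}

#' @rdname ramp_timing
#' @export
timing_conditional <- function(tau, k = 0.1) {
  stopifnot(is.numeric(tau), tau > 0, is.numeric(k), k >= 0)
  structure(
    list(kind = "conditional", tau = tau, k = k, sd = k * tau),
    class = c("timing_conditional", "ramp_timing")
  )
}

#' @rdname ramp_timing
#' @export
timing_fixed <- function(tau) {
  stopifnot(is.numeric(tau), tau > 0)
  structure(
    list(kind = "fixed", tau = tau),
    class = c("timing_fixed", "ramp_timing")
  )
}

#' Density, survival, hazard and transition probability
#'
#' `hazard()` is the instantaneous event rate conditioned on the event not
#' yet having occurred, `pdf(t) / survival(t)`. Where the survival function
#' has decayed below `1e-12` the hazard is numerically meaningless and a
#' declared-undefined sentinel (`NA`) is returned; callers must cap their
#' grids inside the distribution's mass. `transition_prob()` is the
#' probability that the event falls in `(t, t + dt]` given it has not
#' happened by `t`.
#'
#' @param dist A `ramp_timing` object.
#' @param t Time(s) in seconds (>= 0); vectorised.
#' @param dt Positive time slice in seconds (`dt = 0` gives probability 0).
#' @return Numeric vector: a rate per second (`hazard`), probability in
#'   `[0, 1]` (`transition_prob`), density, or survival probability.
#' @export
timing_density <- function(dist, t) UseMethod("timing_density")

#' @export
timing_density.timing_gamma <- function(dist, t) {
  stats::dgamma(t, shape = dist$shape, scale = dist$scale)
}

#' @export
timing_density.timing_conditional <- function(dist, t) {
  z <- stats::pnorm(0, dist$tau, dist$sd, lower.tail = FALSE)
  ifelse(t > 0, stats::dnorm(t, dist$tau, dist$sd) / z, 0)
}

#' @export
timing_density.timing_fixed <- function(dist, t) {
  ifelse(t == dist$tau, Inf, 0)
}

#' @rdname timing_density
#' @export
timing_survival <- function(dist, t) UseMethod("timing_survival")

#' @export
timing_survival.timing_gamma <- function(dist, t) {
  stats::pgamma(t, shape = dist$shape, scale = dist$scale, lower.tail = FALSE)
}

#' @export
timing_survival.timing_conditional <- function(dist, t) {
  z <- stats::pnorm(0, dist$tau, dist$sd, lower.tail = FALSE)
  s <- stats::pnorm(pmax(t, 0), dist$tau, dist$sd, lower.tail = FALSE) / z
  pmin(s, 1)
}

#' @export
timing_survival.timing_fixed <- function(dist, t) {
  ifelse(t < dist$tau, 1, 0)
}

#' @rdname timing_density
#' @export
hazard <- function(dist, t) {
  stopifnot(inherits(dist, "ramp_timing"), all(t >= 0))
  s <- timing_survival(dist, t)
  out <- timing_density(dist, t) / s
  out[s < 1e-12] <- NA_real_
  out
}

#' @rdname timing_density
#' @export
transition_prob <- function(dist, t, dt) {
  stopifnot(inherits(dist, "ramp_timing"), all(t >= 0), all(dt >= 0))
  s0 <- timing_survival(dist, t)
  s1 <- timing_survival(dist, t + dt)
  out <- (s0 - s1) / s0
  out[s0 < 1e-12] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Draw notification times
#'
#' Sampling is deterministic given `seed`; with `seed = NULL` the current RNG
#' stream is used. Conditional (truncated-Gaussian) samples are drawn by
#' inverse-CDF so that a seed maps to the same draws regardless of rejection
#' behaviour.
#'
#' @param dist A `ramp_timing` object.
#' @param n Number of draws (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` positive times in seconds.
#' @export
sample_timing <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "ramp_timing"))
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer.", call. = FALSE)
  }
  if (n == 0L) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  switch(dist$kind,
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    conditional = {
      p0 <- stats::pnorm(0, dist$tau, dist$sd)
      u <- p0 + (1 - p0) * stats::runif(n)
      stats::qnorm(u, dist$tau, dist$sd)
    },
    fixed = rep(dist$tau, n)
  )
}

#' @export
print.ramp_timing <- function(x, ...) {
  desc <- switch(x$kind,
    gamma = sprintf("gamma timing G(shape = %g, scale = %g)", x$shape, x$scale),
    conditional = sprintf(
      "conditional timing N(tau = %g, sd = %g), truncated to T > 0", x$tau, x$sd
    ),
    fixed = sprintf("deterministic timing T = %g s", x$tau)
  )
  cat(desc, "\n")
  invisible(x)
}
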