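#' Softmax latency policy
#'
#' The actor selects a press latency with probability proportional to
#' `exp(beta * Q)`, where `Q` is the relative action value of that latency.
#' Values are max-shifted before exponentiation for numerical stability.
#'
#' @param q Numeric vector of relative action values over `tau_grid`.
#' @param beta Inverse temperature (>= 0).
#' @param tau_grid Ordered positive latencies in seconds.
#' @return A tibble of class `softmax_policy` with columns `tau`, `q`,
#'   `prob`.
#' @examples
#' softmax_policy(c(0, log(2)), beta = 1, tau_grid = c(1, 2))$prob # 1/3, 2/3
#' @export
softmax_policy <- function(q, beta, tau_grid) {
  stopifnot(all(is.finite(q)), beta >= 0, length(q) == length(tau_grid),
            all(tau_grid > 0))
  e <- exp(beta * (q - max(q)))
  out <- tibble::tibble(tau = tau_grid, q = q, prob = e / sum(e))
  class(out) <- c("softmax_policy", class(out))
  out
}

default_tau_grid <- function() exp(seq(log(0.1), log(20), length.out = 200L))

#' Self-consistent average reward under a softmax latency policy
#'
#' The average reward rate `rho` prices the opportunity cost of time inside
#' the action values, `Q(1, tau) = a / tau + b + r - rho * tau + V(2)`, yet
#' itself depends on the latency policy those values induce. The fixed point
#' is found by alternating (i) values from the current `rho`, (ii) the
#' softmax policy from the values, (iii) `rho` from the renewal-reward ratio
#' under that policy, with damped updates.
#'
#' @param spec A `lever_task` (its `a`, `b`, `r`, `tau_post`, `tau_I` are
#'   used; timing is the policy itself here).
#' @param beta Softmax inverse temperature (>= 0).
#' @param tau_grid Candidate latencies in seconds.
#' @param tol Convergence tolerance on `rho`.
#' @param max_iter Iteration cap.
#' @param rho_init Starting value for `rho`.
#' @param damping Damping factor on `rho` updates in (0, 1].
#' @return A list of class `vigour_fixed_point`: `rho`, `policy` (a
#'   `softmax_policy`), `mean_latency`, `delta_cue`, `iterations`,
#'   `converged`, and the iterate trace `rho_trace`.
#' @export
solve_policy_rho_fixed_point <- function(spec, beta = 1,
                                         tau_grid = default_tau_grid(),
                                         tol = 1e-10, max_iter = 500L,
                                         rho_init = 0, damping = 0.5) {
  stopifnot(inherits(spec, "lever_task"), all(tau_grid > 0), tol > 0)
  u <- spec$r + spec$a / tau_grid + spec$b
  cycle <- tau_grid + spec$tau_post + spec$tau_I
  rho <- rho_init
  rho_trace <- numeric(0)
  converged <- FALSE
  pol <- NULL
  for (it in seq_len(max_iter)) {
    q <- u - rho * tau_grid
    pol <- softmax_policy(q, beta, tau_grid)
    rho_new <- sum(pol$prob * u) / sum(pol$prob * cycle)
    rho_next <- (1 - damping) * rho + damping * rho_new
    rho_trace <- c(rho_trace, rho_next)
    if (abs(rho_next - rho) < tol) {
      rho <- rho_next
      converged <- TRUE
      break
    }
    rho <- rho_next
  }
  if (!converged) {
    stop(sprintf(
      "rho fixed point did not converge in %d iterations; last iterates: %s",
      max_iter, paste(signif(utils::tail(rho_trace, 5), 8), collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(
      rho = rho, policy = pol,
      mean_latency = sum(pol$prob * tau_grid),
      delta_cue = sum(pol$prob * u),
      iterations = it, converged = converged, rho_trace = rho_trace,
      spec = spec, beta = beta
    ),
    class = "vigour_fixed_point"
  )
}

#' @export
print.vigour_fixed_point <- function(x, ...) {
  cat(sprintf(
    "softmax latency policy fixed point: rho = %.6g utility/s, mean latency = %.4g s (beta = %g, %d iterations)\n",
    x$rho, x$mean_latency, x$beta, x$iterations
  ))
  invisible(x)
}

#' @export
tidy.vigour_fixed_point <- function(x, ...) x$policy

#' @export
glance.vigour_fixed_point <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, delta_cue = x$delta_cue, mean_latency = x$mean_latency,
    beta = x$beta, iterations = x$iterations, converged = x$converged
  )
}

#' Motivational-state sweep of reward utility
#'
#' Emulates a change in motivational state as a change in the utility `r` of
#' a fixed reward. For each `r` the policy/`rho` fixed point is solved and
#' three quantities recorded: the average utility rate `rho` (the proposed
#' tonic dopamine signal), the TD error at the trial-start cue `delta_cue`
#' (the policy-expected net utility of the announced trial, i.e. the value
#' step from an unvalued between-trials baseline), and the policy's mean
#' latency. Across the sweep, `rho` and `delta_cue` rise together while
#' latency falls — a correlation between phasic response and vigour with no
#' direct mechanistic link between them.
#'
#' @inheritParams solve_policy_rho_fixed_point
#' @param r_values Reward utilities to sweep (non-empty).
#' @return A tibble of class `motivation_sweep` with columns `r`, `rho`,
#'   `delta_cue`, `mean_latency`.
#' @export
sweep_reward_utility <- function(spec, beta = 1, tau_grid = default_tau_grid(),
                                 r_values) {
  stopifnot(length(r_values) >= 1L)
  out <- purrr::map_dfr(r_values, function(r) {
    sp <- spec
    sp$r <- r
    fp <- solve_policy_rho_fixed_point(sp, beta = beta, tau_grid = tau_grid)
    tibble::tibble(r = r, rho = fp$rho, delta_cue = fp$delta_cue,
                   mean_latency = fp$mean_latency)
  })
  class(out) <- c("motivation_sweep", class(out))
  out
}

#' @export
glance.motivation_sweep <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    corr_delta_rho = if (nrow(x) > 1L) stats::cor(x$delta_cue, x$rho) else NA_real_,
    corr_delta_latency = if (nrow(x) > 1L) stats::cor(x$delta_cue, x$mean_latency) else NA_real_
  )
}

#' @export
autoplot.motivation_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rho", "delta_cue", "mean_latency"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "reward utility r", y = NULL)
}
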