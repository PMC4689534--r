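#' Alpha-function dopamine response kernel
#'
#' Models the impulse response converting phasic dopaminergic activity into a
#' change in extracellular dopamine concentration: a punctate prediction error
#' produces a transient `f(t) = (t / xi) * exp(1 - t / xi)` that peaks at 1
#' exactly `xi` seconds after the event and then decays with time constant
#' `xi`. The default `xi = 0.7` s matches voltammetric responses to brief
#' VTA stimulation.
#'
#' The kernel is truncated at `support` seconds; at the default `10 * xi`
#' the discarded tail is below `exp(-9)` of the peak.
#'
#' @param xi Kernel time constant in seconds (> 0).
#' @param dt Grid step in seconds (> 0).
#' @param support Truncation horizon in seconds (>= 5 * xi).
#' @return A tibble of class `drf_kernel` with columns `time_s`, `value`.
#' @examples
#' k <- drf_kernel(xi = 0.7, dt = 0.01)
#' max(k$value) # 1 at t = xi
#' @export
drf_kernel <- function(xi = 0.7, dt = 0.01, support = 10 * xi) {
  if (!is.numeric(xi) || length(xi) != 1L || !is.finite(xi) || xi <= 0) {
    stop("`xi` must be a single positive number (seconds).", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds).", call. = FALSE)
  }
  if (support < 5 * xi) {
    stop("`support` must be at least 5 * xi seconds.", call. = FALSE)
  }
  t <- seq(0, support, by = dt)
  out <- tibble::tibble(time_s = t, value = (t / xi) * exp(1 - t / xi))
  attr(out, "xi") <- xi
  attr(out, "dt") <- dt
  class(out) <- c("drf_kernel", class(out))
  out
}

#' Asymmetric scaling of negative prediction errors
#'
#' Fluctuations in dopamine concentration need not encode positive and
#' negative prediction errors symmetrically: negative errors appear to be
#' reported by pauses in burst firing and reach the concentration signal
#' attenuated. `rectify_errors()` leaves non-negative samples unchanged and
#' multiplies negative samples by `d` (with `d = 1` the identity, and the
#' conventional asymmetric choice `d = 1/6`).
#'
#' @param trace A `ramp_ts` of phasic TD errors.
#' @param d Scale applied to negative samples, in (0, 1].
#' @return A `ramp_ts` on the same grid.
#' @export
rectify_errors <- function(trace, d = 1 / 6) {
  stopifnot(inherits(trace, "ramp_ts"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 || d > 1) {
    stop("`d` must be a single number in (0, 1].", call. = FALSE)
  }
  dplyr::mutate(trace, value = ifelse(.data$value >= 0, .data$value, d * .data$value))
}

#' Convolve a phasic activity trace with the response kernel
#'
#' Discrete causal convolution scaled by the grid step, so that the output
#' amplitude is set by impulse *area* rather than sample height: a unit-area
#' impulse (one sample of height `1/dt`) maps onto the kernel itself. The
#' output shares the input grid; the causal tail beyond it is dropped.
#'
#' @param trace A `ramp_ts`.
#' @param kernel A `drf_kernel` on the same grid step.
#' @return A `ramp_ts` on the grid of `trace`.
#' @export
convolve_drf <- function(trace, kernel) {
  stopifnot(inherits(trace, "ramp_ts"), inherits(kernel, "drf_kernel"))
  dt <- attr(kernel, "dt")
  ts_step <- ts_dt(trace)
  if (!is.na(ts_step) && abs(ts_step - dt) > 1e-9 * dt) {
    stop("`trace` and `kernel` must share the same grid step.", call. = FALSE)
  }
  n <- nrow(trace)
  full <- dt * stats::convolve(trace$value, rev(kernel$value), type = "open")
  dplyr::mutate(trace, value = full[seq_len(n)])
}

#' Event-aligned trial averaging
#'
#' Re-indexes each trace so that its alignment event sits at time zero,
#' then averages across trials on a common window grid. Standard errors use
#' the n - 1 sample standard deviation divided by the square root of the
#' number of contributing trials. Traces that do not cover the window after
#' shifting are excluded with a warning.
#'
#' @param traces List of `ramp_ts` objects sharing a grid step.
#' @param align_times Numeric vector of event times (seconds), one per trace.
#' @param window Length-2 numeric `c(pre, post)`: seconds covered before and
#'   after the event (both non-negative).
#' @return A tibble of class `aligned_avg` with columns `time_s`, `mean`,
#'   `sem`, and attribute `n` (number of trials averaged).
#' @export
aligned_average <- function(traces, align_times, window) {
  if (length(traces) == 0L) stop("`traces` must be non-empty.", call. = FALSE)
  if (length(traces) != length(align_times)) {
    stop("`traces` and `align_times` must have equal length.", call. = FALSE)
  }
  stopifnot(length(window) == 2L, all(window >= 0))
  dt <- ts_dt(traces[[1L]])
  pre <- window[1L]
  post <- window[2L]
  n_pre <- round(pre / dt)
  n_post <- round(post / dt)
  rel_t <- dt * seq(-n_pre, n_post)
  rows <- purrr::map2(traces, align_times, function(ts, t_ev) {
    i_ev <- round((t_ev - ts$time_s[1L]) / dt) + 1L
    idx <- i_ev + seq(-n_pre, n_post)
    if (idx[1L] < 1L || idx[length(idx)] > nrow(ts)) return(NULL)
    ts$value[idx]
  })
  keep <- !purrr::map_lgl(rows, is.null)
  if (!all(keep)) {
    warning(sprintf("%d trace(s) excluded: window not covered after alignment.",
                    sum(!keep)), call. = FALSE)
  }
  rows <- rows[keep]
  if (length(rows) == 0L) stop("No trace covers the requested window.", call. = FALSE)
  m <- do.call(rbind, rows)
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1L) apply(m, 2L, stats::sd) / sqrt(n) else rep(0, ncol(m))
  out <- tibble::tibble(time_s = rel_t, mean = mu, sem = sem)
  attr(out, "n") <- n
  class(out) <- c("aligned_avg", class(out))
  out
}

#' @export
autoplot.aligned_avg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "mean ± SEM")
}
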