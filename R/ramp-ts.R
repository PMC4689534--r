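#' Uniformly sampled signal traces
#'
#' A `ramp_ts` is the universal currency of the package: a tibble with columns
#' `time_s` and `value` on a uniform time grid, used for TD-error traces,
#' gain paths and modelled dopamine concentration signals alike.
#'
#' @param value Numeric vector of samples (finite, length >= 1).
#' @param dt Grid step in seconds (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `ramp_ts` with columns `time_s` and `value`.
#' @examples
#' ts <- ramp_ts(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.01)
#' ts_dt(ts)
#' @export
ramp_ts <- function(value, dt, t0 = 0) {
  stopifnot(is.numeric(value), length(value) >= 1L)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds).", call. = FALSE)
  }
  if (!all(is.finite(value))) {
    stop("`value` must contain only finite samples.", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = t0 + dt * (seq_along(value) - 1L),
    value = as.double(value)
  )
  class(out) <- c("ramp_ts", class(out))
  out
}

#' Coerce a two-column data frame to a `ramp_ts`
#'
#' The time column must be uniformly spaced; the grid step is inferred.
#'
#' @param x A data frame with columns `time_s` and `value`.
#' @param tol Relative tolerance on grid uniformity.
#' @return A `ramp_ts`.
#' @export
as_ramp_ts <- function(x, tol = 1e-8) {
  stopifnot(is.data.frame(x), all(c("time_s", "value") %in% names(x)))
  t <- x$time_s
  if (length(t) > 1L) {
    steps <- diff(t)
    dt <- stats::median(steps)
    if (dt <= 0 || any(abs(steps - dt) > tol * max(dt, 1))) {
      stop("`time_s` is not a uniform grid.", call. = FALSE)
    }
  } else {
    dt <- NA_real_
  }
  out <- tibble::tibble(time_s = as.double(t), value = as.double(x$value))
  class(out) <- c("ramp_ts", class(out))
  out
}

#' Grid step of a trace
#' @param ts A `ramp_ts`.
#' @return The grid step in seconds (`NA` for a length-1 trace).
#' @export
ts_dt <- function(ts) {
  if (nrow(ts) < 2L) return(NA_real_)
  (ts$time_s[nrow(ts)] - ts$time_s[1L]) / (nrow(ts) - 1L)
}

#' Read / write a trace as a two-column CSV
#'
#' The on-disk format is a plain CSV with a one-line header `time_s,value`.
#'
#' @param ts A `ramp_ts`.
#' @param path File path.
#' @return `write_ramp_ts()` returns `path` invisibly; `read_ramp_ts()`
#'   returns a `ramp_ts`.
#' @export
write_ramp_ts <- function(ts, path) {
  readr::write_csv(tibble::as_tibble(ts)[, c("time_s", "value")], path)
  invisible(path)
}

#' @rdname write_ramp_ts
#' @export
read_ramp_ts <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    value = readr::col_double()
  ))
  as_ramp_ts(x)
}

#' @export
autoplot.ramp_ts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "value")
}
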