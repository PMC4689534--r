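# Brute-force double-loop causal convolution (independent oracle for
# convolve_drf): out[i] = dt * sum_j x[j] * k[i - j + 1]
naive_convolve <- function(x, k, dt) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      ki <- i - j + 1L
      if (ki <= length(k)) out[i] <- out[i] + x[j] * k[ki]
    }
  }
  dt * out
}

# Monte-Carlo estimate of the microstate relative value V({1, t_hat}) by
# direct sampling of the residual wait: draw T | T > t_hat by rejection and
# average -rho * (T - t_hat), then add the preparedness value.
mc_relative_value <- function(table, t_hat, n = 2e4) {
  tim <- table$timing
  draws <- numeric(0)
  while (length(draws) < n) {
    x <- sample_timing(tim, n)
    draws <- c(draws, x[x > t_hat])
  }
  draws <- draws[seq_len(n)]
  est <- table$v2 - table$rho * mean(draws - t_hat)
  se <- table$rho * stats::sd(draws - t_hat) / sqrt(n)
  list(value = est, se = abs(se))
}

# Closed-form mean decision time of the constant-gain symmetric DDM
# started at 0: (z/A) * tanh(z * A / c^2); with constant gain g both drift
# and noise scale by g.
ddm_mean_dt <- function(A, c, z, g = 1) {
  (z / (g * A)) * tanh(z * A / (g * c^2))
}

# first interior local maximum of Q on a dense latency grid (the optimal
# latency of the discounted problem; the tail limit Q -> 0 is not a press)
grid_local_argmax <- function(a, gamma, taus) {
  q <- a / taus + gamma^taus
  n <- length(q)
  i <- which(q[2:(n - 1L)] > q[1:(n - 2L)] & q[2:(n - 1L)] >= q[3:n]) + 1L
  if (length(i) == 0L) return(NA_real_)
  taus[i[1L]]
}

impulse_area <- function(trace, event_name) {
  ev <- trace$events[trace$events$event == event_name, ]
  sum(ev$area)
}
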