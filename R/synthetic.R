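#' Draw uniform stimuli
#'
#' Stimuli are uniform on `[0, 1)^D`, the maximum-entropy (worst-case) prior
#' on the periodic domain.
#'
#' @param D stimulus dimensionality.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return an `n x D` matrix (drop to a vector with `n = 1` and `drop = TRUE`).
#' @param drop return a plain vector when `n == 1`.
#' @export
sample_stimulus <- function(D, n = 1, seed = NULL, drop = TRUE) {
  s <- with_seed(seed, matrix(runif(n * D), n, D))
  if (n == 1 && drop) as.numeric(s) else s
}

#' Sample Poisson spike counts for one trial
#'
#' Counts are conditionally independent given the stimulus:
#' `r_i ~ Poisson(T * f_i(s))`.
#'
#' @param pop a `neural_population`.
#' @param s stimulus vector in `[0, 1)^D`.
#' @param T decoding-window length in seconds (>= 0).
#' @param seed optional integer seed.
#' @return a `spike_count_obs`: counts, window `T`, true stimulus, seed.
#' @export
sample_spike_counts <- function(pop, s, T, seed = NULL) {
  stopifnot(T >= 0)
  f <- population_rates(pop, s)
  counts <- with_seed(seed, rpois(pop$N, T * f))
  structure(list(counts = counts, T = T, s = as.numeric(s), seed = seed),
            class = "spike_count_obs")
}

#' Ornstein-Uhlenbeck stimulus trace
#'
#' Integrates `ds/dt = -s/tau_s + sqrt(2 sigma_s^2 / tau_s) xi(t)` by
#' Euler-Maruyama on the simulation clock and wraps the trace onto `[0, 1)`.
#' The drift acts on the unwrapped coordinate (mean reversion toward the
#' stimulus 0 on the circle), so the wrapped trace has a stationary wrapped
#' normal law with circular standard deviation `sigma_s` around 0.
#'
#' @param tau_s relaxation time (s).
#' @param sigma_s stationary standard deviation (stimulus units).
#' @param duration trace length (s).
#' @param dt integration step (s); defaults to the 0.1 ms network clock.
#' @param s0 initial (unwrapped) value.
#' @param seed optional integer seed.
#' @return data.frame with `time`, wrapped `s`, and the unwrapped `s_raw`.
#' @export
ou_stimulus <- function(tau_s = 0.5, sigma_s = 0.1, duration = 1,
                        dt = 1e-4, s0 = 0, seed = NULL) {
  stopifnot(tau_s > 0, sigma_s >= 0, dt > 0, duration >= 0)
  n <- floor(duration / dt)
  if (n == 0) {
    return(data.frame(time = numeric(0), s = numeric(0), s_raw = numeric(0)))
  }
  noise <- with_seed(seed, rnorm(n - 1))
  x <- numeric(n)
  x[1] <- s0
  amp <- sqrt(2 * sigma_s^2 / tau_s) * sqrt(dt)
  for (k in seq_len(n - 1)) {
    x[k + 1] <- x[k] - x[k] / tau_s * dt + amp * noise[k]
  }
  data.frame(time = (seq_len(n) - 1) * dt, s = wrap_unit(x), s_raw = x)
}

#' Step-change stimulus trace
#'
#' The stimulus sits at 0.25 and jumps to 0.75 at `t_switch`.
#'
#' @param t_switch switch time (s).
#' @param duration trace length (s).
#' @param dt sampling step (s).
#' @return data.frame with `time` and `s`.
#' @export
step_stimulus <- function(t_switch, duration, dt = 1e-4) {
  stopifnot(dt > 0, duration >= 0)
  n <- floor(duration / dt)
  tm <- (seq_len(n) - 1) * dt
  data.frame(time = tm, s = ifelse(tm < t_switch, 0.25, 0.75))
}

#' Write a stimulus trace or spike counts as CSV
#'
#' @param x a stimulus trace data.frame (`time`, `s`) or `spike_count_obs`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  if (inherits(x, "spike_count_obs")) {
    x <- data.frame(neuron_id = seq_along(x$counts), count = x$counts)
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
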