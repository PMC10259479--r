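#' Scaling predictor for the minimal decoding time with L modules
#'
#' Up to a width-dependent constant (absorbed into the fitted regressor), the
#' minimal decoding time of an L-module population without ongoing activity
#' scales as
#' `(1/(a N)) * exp(D/w) * B0(1/w)^-(D-1) * mean(lambda^-3)^2 / mean(lambda^-2)^3`.
#' The derivation assumes approximately equal amplitudes and a unique root of
#' the likelihood equations, so it does not capture ambiguous codes.
#'
#' @param periods module periods replicated per neuron, or module periods with
#'   equal module sizes (only their distribution matters).
#' @param D stimulus dimensionality.
#' @param w tuning width.
#' @param a amplitude (use the family-average amplitude).
#' @param N population size.
#' @return predictor in seconds, up to the fitted constant.
#' @export
t_th_scaling <- function(periods, D, w, a, N) {
  stopifnot(all(periods > 0), a > 0, N >= 1)
  iw <- 1 / w
  (1 / (a * N)) * exp(D * iw) * besselI(iw, 0)^(-(D - 1)) *
    mean(periods^-3)^2 / mean(periods^-2)^3
}

#' Scale-factor form of the scaling predictor
#'
#' For `L` equal-size modules with periods in geometric progression
#' (`lambda_j = lambda1 * c^(j-1)`) the period terms reduce to
#' `(sum_j c^-3j)^2 / (sum_j c^-2j)^3`, independent of `lambda1`, and the
#' predictor becomes
#' `exp(D/w) / (a M B0(1/w)^(D-1)) * (sum c^-3j)^2 / (sum c^-2j)^3`.
#'
#' @param c scale factor(s), vectorized.
#' @param L number of modules.
#' @param D stimulus dimensionality.
#' @param w tuning width.
#' @param a amplitude (family average).
#' @param M neurons per module.
#' @return predictor values (seconds, up to the fitted constant).
#' @export
scaling_predictor <- function(c, L, D, w, a, M) {
  j <- 0:(L - 1)
  s3 <- vapply(c, function(ci) sum(ci^(-3 * j)), numeric(1))
  s2 <- vapply(c, function(ci) sum(ci^(-2 * j)), numeric(1))
  exp(D / w) / (a * M * besselI(1 / w, 0)^(D - 1)) * s3^2 / s2^3
}

#' Fit the two theory constants of the scaling law
#'
#' Ordinary least squares of simulated minimal decoding times on the
#' [scaling_predictor()]: `T_th ~ K1 * x(c) + K2`. The width-dependent
#' prefactor of the theory is absorbed into `K1`.
#'
#' @param c_values scale factors of the fitted family (shared `lambda1`, `D`,
#'   `b`); at least 3.
#' @param t_th simulated minimal decoding times (same units as desired for
#'   `K2`, e.g. ms).
#' @param L,D,w,a,M family parameters passed to [scaling_predictor()].
#' @return a `theory_fit`: `K1`, `K2`, `r_squared`, fitted values, residuals
#'   and the predictor values.
#' @export
fit_theory_constants <- function(c_values, t_th, L, D, w, a, M) {
  stopifnot(length(c_values) == length(t_th), length(c_values) >= 3)
  x <- scaling_predictor(c_values, L, D, w, a, M)
  if (sd(x) == 0) stop("rank-deficient design: constant predictor")
  fit <- lm(t_th ~ x)
  r2 <- 1 - sum(resid(fit)^2) / sum((t_th - mean(t_th))^2)
  structure(list(K1 = unname(coef(fit)[2]), K2 = unname(coef(fit)[1]),
                 r_squared = r2,
                 fitted = unname(fitted(fit)), residuals = unname(resid(fit)),
                 predictor = x, c_values = c_values, t_th = t_th,
                 family = list(L = L, D = D, w = w, a = a, M = M)),
            class = "theory_fit")
}

#' Expected population spike count at the minimal decoding time
#'
#' `T_th` times the summed mean rate (evoked plus baseline) of all neurons:
#' the number of spikes the population needs before its signal is reliable.
#'
#' @param pop a `neural_population`.
#' @param T_th minimal decoding time in seconds.
#' @return expected total spike count.
#' @export
mean_spike_count_at_threshold <- function(pop, T_th) {
  stopifnot(T_th >= 0)
  T_th * sum(evoked_mean_rates(pop) + pop$b)
}

#' @export
print.theory_fit <- function(x, ...) {
  cat(sprintf("Scaling-law fit: K1 = %.4g, K2 = %.4g, R^2 = %.4f (n = %d)\n",
              x$K1, x$K2, x$r_squared, length(x$t_th)))
  invisible(x)
}
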