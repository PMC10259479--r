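#' Log-likelihood of a spike-count observation
#'
#' Stimulus-dependent terms only:
#' `V(r; s) = sum_i r_i * log(T * f_i(s)) - T * f_i(s)`.
#' A neuron with `r_i > 0` but zero rate yields `-Inf` (a valid score, not an
#' error).
#'
#' @param r spike counts (vector of length `N`) or a `spike_count_obs`.
#' @param s stimulus vector; reduced mod 1.
#' @param pop a `neural_population`.
#' @param T decoding time (s); taken from the observation if `r` is one.
#' @return scalar log-likelihood value.
#' @export
log_likelihood <- function(r, s, pop, T = NULL) {
  if (inherits(r, "spike_count_obs")) {
    if (is.null(T)) T <- r$T
    r <- r$counts
  }
  stopifnot(length(r) == pop$N, !is.null(T))
  loglik_cpp(pop_pack(pop), as.numeric(r), wrap_unit(as.numeric(s)), T)
}

#' Maximum-likelihood stimulus decoding
#'
#' Implements a combined grid/simplex search of the non-concave likelihood
#' surface: (1) draw `n_candidates` uniform stimulus conditions, (2) keep the
#' four with the largest log-likelihood, (3) add the true stimulus as a fifth
#' starting point (a conservative choice: it can hide, but never inflate,
#' threshold distortion), (4) run an unconstrained Nelder-Mead simplex from
#' each start, (5) return the best local optimum, ties within the function
#' tolerance broken toward the true stimulus, (6) wrap componentwise mod 1.
#'
#' @param r spike counts (length `N`) or a `spike_count_obs`.
#' @param pop a `neural_population`.
#' @param T decoding time (s).
#' @param s_true true stimulus (always added to the start set).
#' @param seed optional seed for the candidate draw.
#' @param candidates optional explicit candidate matrix (`n x D`), replacing
#'   the random draw (useful for equivariance checks).
#' @param n_candidates number of random starting candidates.
#' @param ptol,ftol,maxit simplex parameter/function tolerances and iteration
#'   cap; recorded in the result.
#' @return a `decode_result`: `s_ml` in `[0,1)^D`, the pre-wrap optimum,
#'   the log-likelihood at the optimum, and per-dimension squared circular
#'   errors `eps2`.
#' @export
decode_ml <- function(r, pop, T = NULL, s_true, seed = NULL,
                      candidates = NULL, n_candidates = 100,
                      ptol = 1e-6, ftol = 1e-8, maxit = 2000) {
  if (inherits(r, "spike_count_obs")) {
    if (is.null(T)) T <- r$T
    if (missing(s_true)) s_true <- r$s
    r <- r$counts
  }
  stopifnot(!is.null(T), length(r) == pop$N, length(s_true) == pop$D)
  if (is.null(candidates)) {
    candidates <- with_seed(seed, matrix(runif(n_candidates * pop$D),
                                         n_candidates, pop$D))
  }
  candidates <- as.matrix(candidates)
  out <- decode_one_cpp(pop_pack(pop), as.numeric(r), T,
                        as.numeric(s_true), candidates, ptol, ftol,
                        as.integer(maxit))
  n_starts <- min(4, nrow(candidates)) + 1
  if (out$n_converged < n_starts) {
    warning(sprintf("%d of %d simplex starts did not converge and were discarded",
                    n_starts - out$n_converged, n_starts))
  }
  structure(list(s_ml = out$s_hat, s_prewrap = out$s_prewrap,
                 log_likelihood = out$value, eps2 = out$eps2,
                 n_starts = n_starts, n_converged = out$n_converged,
                 control = list(ptol = ptol, ftol = ftol, maxit = maxit)),
            class = "decode_result")
}

#' Squared circular estimation error per stimulus dimension
#'
#' `eps2_j = min((s_j - shat_j)^2, (s_j - shat_j + 1)^2, (s_j - shat_j - 1)^2)`,
#' the squared distance on the unit circle; at most 0.25 per dimension.
#'
#' @param s true stimulus vector in `[0,1)^D`.
#' @param s_hat estimate in `[0,1)^D`.
#' @return vector of squared errors.
#' @export
circular_error <- function(s, s_hat) {
  d <- s - s_hat
  pmin(d^2, (d + 1)^2, (d - 1)^2)
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("ML decode: s_ml = (%s), logLik = %.4f, rmse = %.4g\n",
              paste(signif(x$s_ml, 6), collapse = ", "),
              x$log_likelihood, sqrt(mean(x$eps2))))
  invisible(x)
}
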