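#' Geometric progression of module spatial periods
#'
#' Module `j` has spatial period `lambda1 * c^(j-1)`; `c = 1` gives `L` copies
#' of the same period, `c < 1` a strictly decreasing (grid-like) progression.
#' Combinations known to produce an ambiguous code over the unit stimulus
#' interval are rejected: for `lambda1 = 1/2` the scale factors
#' `c = 1, 1/2, 1/3, 1/4, ...` make the periods commensurate so that distinct
#' stimuli share identical population responses.
#'
#' @param lambda1 largest spatial period, in `(0, 1]`.
#' @param c scale factor between successive modules, in `(0, 1]`.
#' @param L number of modules (>= 1).
#' @return numeric vector of `L` periods.
#' @export
#' @examples
#' module_periods(1, 0.7, 2)
module_periods <- function(lambda1, c, L) {
  stopifnot(lambda1 > 0, lambda1 <= 1, c > 0, c <= 1, L >= 1)
  if (L > 1 && abs(lambda1 - 0.5) < 1e-12 && is_near_integer(1 / c)) {
    stop("ambiguous code: lambda1 = 1/2 with scale factor 1/",
         round(1 / c), " cannot span the stimulus interval uniquely")
  }
  lambda1 * c^(seq_len(L) - 1)
}

#' Tuning-curve parameters
#'
#' @param a peak evoked amplitude (spikes/s).
#' @param w width scale of the cosine exponent (dimensionless).
#' @param lambda spatial period as a fraction of the unit domain, `(0, 1]`.
#' @param pref preferred location(s), vector in `[0, 1)^D`.
#' @param b baseline (ongoing) rate, spikes/s.
#' @return a `tuning_params` list.
#' @export
tuning_params <- function(a, w, lambda, pref, b = 0) {
  stopifnot(a > 0, w > 0, lambda > 0, lambda <= 1, b >= 0,
            all(pref >= 0), all(pref < 1))
  structure(list(a = a, w = w, lambda = lambda, pref = as.numeric(pref), b = b),
            class = "tuning_params")
}

#' Evaluate a circular tuning curve
#'
#' The mean firing rate at stimulus `s` is
#' `a * prod_j exp((1/w) * (cos(2*pi*(s_j - pref_j)/lambda) - 1)) + b`,
#' a von Mises-like bump (or comb of bumps for `lambda < 1`) on each stimulus
#' dimension. The rate always lies in `[b, a + b]`.
#'
#' @param params a [tuning_params()] object.
#' @param s stimulus: vector of length `D`, or an `n x D` matrix.
#' @return rate(s) in spikes/s.
#' @export
tuning_rate <- function(params, s) {
  if (is.matrix(s)) {
    z <- cos(2 * pi * sweep(s, 2, params$pref, "-") / params$lambda) - 1
    params$a * exp(rowSums(z) / params$w) + params$b
  } else {
    z <- cos(2 * pi * (s - params$pref) / params$lambda) - 1
    params$a * exp(sum(z) / params$w) + params$b
  }
}

# Mean over [0,1) of the 1-D evoked tuning profile (amplitude 1). For integer
# 1/lambda this is exp(-1/w) * besselI(1/w, 0); otherwise the unit interval
# covers a partial period and the mean depends on the preferred location, so
# adaptive quadrature is used.
mean_profile_1d <- function(lambda, pref, w, rel_tol = 1e-10) {
  if (is_near_integer(1 / lambda)) {
    return(exp(-1 / w) * besselI(1 / w, 0))
  }
  f <- function(s) exp((cos(2 * pi * (s - pref) / lambda) - 1) / w)
  out <- tryCatch(
    integrate(f, 0, 1, rel.tol = rel_tol, subdivisions = 500L),
    error = function(e) stop("quadrature failure in amplitude normalization: ",
                             conditionMessage(e)))
  out$value
}

#' Sample preferred tuning locations
#'
#' Locations are drawn independently and uniformly on `[0, 1)^D`. When several
#' populations are compared, sample once and pass the same matrix to each so
#' the populations differ only in their spatial periods.
#'
#' @param N number of neurons.
#' @param D stimulus dimensionality.
#' @param seed integer seed (optional; the caller's RNG state is restored).
#' @return `N x D` matrix.
#' @export
sample_preferred_locations <- function(N, D, seed = NULL) {
  stopifnot(N >= 1, D >= 1)
  with_seed(seed, matrix(runif(N * D), N, D))
}

#' Construct a modular population of circular tuning curves
#'
#' Builds `N` neurons organized in `L` modules whose spatial periods follow
#' [module_periods()]. Unless `normalize = FALSE`, each neuron's amplitude is
#' solved (one adaptive quadrature per neuron and dimension, exploiting the
#' separability of the tuning curve) so that its mean evoked rate over the
#' stimulus domain equals `fbar_stim`. The default target rate
#' `20 * exp(-D/w) * besselI(1/w, 0)^D` spikes/s corresponds to a peak
#' amplitude of 20 spikes/s for a single-peaked neuron with an integer number
#' of peaks per dimension.
#'
#' @param N neurons in total; must be a multiple of `L`.
#' @param D stimulus dimensionality.
#' @param lambda1 largest spatial period.
#' @param c module scale factor.
#' @param L number of modules.
#' @param w tuning width parameter.
#' @param b baseline (ongoing) rate, spikes/s.
#' @param fbar_stim target mean evoked rate, spikes/s.
#' @param prefs optional `N x D` matrix of preferred locations (shared draws).
#' @param seed seed used when `prefs` is not given.
#' @param normalize solve amplitudes for equal mean evoked rate?
#' @param amplitude fixed amplitude used when `normalize = FALSE`.
#' @return a `neural_population` object.
#' @export
build_population <- function(N, D = 1, lambda1 = 1, c = 1, L = 1, w = 0.3,
                             b = 0, fbar_stim = NULL, prefs = NULL,
                             seed = NULL, normalize = TRUE, amplitude = 20) {
  stopifnot(N >= 1, D >= 1, b >= 0, w > 0)
  periods <- module_periods(lambda1, c, L)
  if (N %% L != 0) stop("N must be a multiple of the number of modules L")
  M <- N %/% L
  module <- rep(seq_len(L), each = M)
  if (is.null(prefs)) {
    prefs <- sample_preferred_locations(N, D, seed = derive_seed(
      if (is.null(seed)) 1L else seed, "prefs"))
  }
  prefs <- as.matrix(prefs)
  stopifnot(nrow(prefs) == N, ncol(prefs) == D)
  if (is.null(fbar_stim)) fbar_stim <- 20 * exp(-D / w) * besselI(1 / w, 0)^D
  pop <- structure(list(
    N = N, D = D, w = w, b = b,
    layout = list(lambda1 = lambda1, c = c, L = L, M = M, periods = periods),
    module = module, lambda = periods[module], prefs = prefs,
    a = rep(amplitude, N), fbar_stim = fbar_stim, seed = seed
  ), class = "neural_population")
  if (normalize) pop <- normalize_amplitudes(pop) else pop
}

#' Set amplitudes for an equal mean evoked rate across neurons
#'
#' Solves each neuron's amplitude so that its evoked (baseline-free) mean rate
#' over `[0,1)^D` equals `pop$fbar_stim`. The mean factorizes across
#' dimensions, so one 1-D quadrature per neuron and dimension suffices.
#'
#' @param pop a `neural_population`.
#' @param fbar_stim optional new target rate (spikes/s).
#' @return the population with amplitudes replaced.
#' @export
normalize_amplitudes <- function(pop, fbar_stim = NULL) {
  stopifnot(inherits(pop, "neural_population"))
  if (!is.null(fbar_stim)) pop$fbar_stim <- fbar_stim
  m <- vapply(seq_len(pop$N), function(i) {
    prod(vapply(seq_len(pop$D), function(j)
      mean_profile_1d(pop$lambda[i], pop$prefs[i, j], pop$w), numeric(1)))
  }, numeric(1))
  pop$a <- pop$fbar_stim / m
  pop
}

#' Mean evoked rate of every neuron over the stimulus domain
#'
#' @param pop a `neural_population`.
#' @return numeric vector of length `N` (spikes/s, baseline excluded).
#' @export
evoked_mean_rates <- function(pop) {
  vapply(seq_len(pop$N), function(i) {
    pop$a[i] * prod(vapply(seq_len(pop$D), function(j)
      mean_profile_1d(pop$lambda[i], pop$prefs[i, j], pop$w), numeric(1)))
  }, numeric(1))
}

#' Population rate vector at a stimulus
#'
#' @param pop a `neural_population`.
#' @param s stimulus vector in `[0, 1)^D`.
#' @return rates of all `N` neurons (spikes/s).
#' @export
population_rates <- function(pop, s) {
  rates_cpp(pop_pack(pop), wrap_unit(as.numeric(s)))
}

# Pack a population into the flat structure the C++ kernels consume.
# cos/sin of 2*pi*pref/lambda are precomputed so that each likelihood
# evaluation needs only L*D trig calls plus one exp per neuron.
pop_pack <- function(pop) {
  ang <- 2 * pi * pop$prefs / pop$lambda
  list(N = pop$N, D = pop$D, L = pop$layout$L, w = pop$w, b = pop$b,
       a = as.numeric(pop$a), module_id = as.integer(pop$module - 1L),
       lambda_m = as.numeric(pop$layout$periods),
       cosphi = cos(ang), sinphi = sin(ang))
}

#' @export
print.neural_population <- function(x, ...) {
  cat("Modular tuning-curve population\n")
  cat(sprintf("  N = %d neurons, D = %d, L = %d module(s) of %d\n",
              x$N, x$D, x$layout$L, x$layout$M))
  cat(sprintf("  periods: %s (lambda1 = %g, c = %g)\n",
              paste(signif(x$layout$periods, 4), collapse = ", "),
              x$layout$lambda1, x$layout$c))
  cat(sprintf("  w = %g, baseline b = %g sp/s, mean evoked rate = %.3f sp/s\n",
              x$w, x$b, x$fbar_stim))
  invisible(x)
}

#' Serialize / restore a population as JSON
#'
#' Amplitudes are stored post-normalization, so the restored object evaluates
#' identically without re-running the quadrature.
#'
#' @param pop a `neural_population`.
#' @param path file path.
#' @return `population_to_json` returns `path` invisibly;
#'   `population_from_json` returns the population.
#' @export
population_to_json <- function(pop, path) {
  obj <- list(N = pop$N, D = pop$D, w = pop$w, b = pop$b,
              layout = pop$layout, prefs = pop$prefs, a = pop$a,
              fbar_stim = pop$fbar_stim, seed = pop$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname population_to_json
#' @export
population_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pop <- build_population(N = obj$N, D = obj$D, lambda1 = obj$layout$lambda1,
                          c = obj$layout$c, L = obj$layout$L, w = obj$w,
                          b = obj$b, fbar_stim = obj$fbar_stim,
                          prefs = matrix(obj$prefs, obj$N, obj$D),
                          normalize = FALSE)
  pop$a <- as.numeric(obj$a)
  pop$seed <- obj$seed
  pop
}
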