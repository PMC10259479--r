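#' Closed-form Fisher information per stimulus dimension
#'
#' For equal amplitudes and no baseline activity, the Fisher information of a
#' large population of circular tuning curves is, per dimension,
#' `J = (2*pi)^2 * a * T * N / w * B0(1/w)^(D-1) * B1(1/w) * exp(-D/w) * mean(lambda^-2)`
#' where `B0`, `B1` are modified Bessel functions of the first kind. Because
#' the expression assumes no baseline it refuses populations with `b > 0`
#' (use [empirical_fisher()] there). If amplitudes are unequal (as after
#' normalization with non-integer numbers of peaks), the population mean
#' amplitude is used.
#'
#' @param pop a `neural_population` with `b = 0`.
#' @param T decoding time (s).
#' @param a amplitude override; defaults to `mean(pop$a)`.
#' @return scalar per-dimension Fisher information, units (unit stimulus)^-2.
#' @export
analytic_fisher <- function(pop, T = 1, a = NULL) {
  stopifnot(inherits(pop, "neural_population"), T >= 0)
  if (pop$b != 0) {
    stop("analytic Fisher information is only valid without ongoing activity (b = 0); ",
         "use empirical_fisher()")
  }
  if (is.null(a)) a <- mean(pop$a)
  iw <- 1 / pop$w
  (2 * pi)^2 * a * T * pop$N / pop$w *
    besselI(iw, 0)^(pop$D - 1) * besselI(iw, 1) * exp(-pop$D * iw) *
    mean(pop$lambda^-2)
}

#' Monte-Carlo (empirical) Fisher information matrix
#'
#' For independent Poisson counts the Fisher matrix at stimulus `s` is
#' `J_kl(s) = T * sum_i (df_i/ds_k)(df_i/ds_l) / f_i(s)`, with the tuning
#' derivatives in closed form. The matrix is averaged element-wise over
#' `n_stimuli` uniformly sampled stimulus conditions; it is valid for any
#' baseline `b >= 0` and is the benchmark used by the minimal-decoding-time
#' criterion whenever `b > 0`.
#'
#' @param pop a `neural_population`.
#' @param T decoding time (s); the matrix is exactly linear in `T`.
#' @param n_stimuli number of Monte-Carlo stimulus draws.
#' @param seed optional integer seed.
#' @return a `fisher_matrix` object: the `D x D` matrix `J`, its
#'   time-normalized version `J_norm = J / T`, and provenance fields.
#' @export
empirical_fisher <- function(pop, T = 1, n_stimuli = 10000, seed = NULL) {
  stopifnot(inherits(pop, "neural_population"), T >= 0, n_stimuli >= 1)
  Jn <- with_seed(seed, fisher_mc_cpp(pop_pack(pop), as.integer(n_stimuli)))
  structure(list(J = T * Jn, J_norm = Jn, T = T, time_normalized = (T == 1),
                 n_stimuli = n_stimuli, seed = seed,
                 population = list(N = pop$N, D = pop$D,
                                   periods = pop$layout$periods, b = pop$b)),
            class = "fisher_matrix")
}

#' Cramer-Rao floor on the per-dimension mean squared error
#'
#' @param fisher a `fisher_matrix` (or plain matrix).
#' @param T decoding time (s); applied on top of a time-normalized matrix.
#' @return mean of `diag(J(T)^-1)` across dimensions.
#' @export
cr_floor <- function(fisher, T = NULL) {
  J <- if (inherits(fisher, "fisher_matrix")) {
    if (!is.null(T)) T * fisher$J_norm else fisher$J
  } else {
    if (!is.null(T)) T * fisher else fisher
  }
  mean(diag(solve(J)))
}

#' @export
print.fisher_matrix <- function(x, ...) {
  cat(sprintf("Empirical Fisher matrix (T = %g s, %d stimuli)\n", x$T, x$n_stimuli))
  print(x$J)
  invisible(x)
}

#' Serialize a Fisher matrix with provenance
#'
#' @param fisher a `fisher_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
fisher_to_json <- function(fisher, path) {
  jsonlite::write_json(unclass(fisher), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
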