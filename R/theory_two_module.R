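#' Maximal tolerable displacement between two modules' estimates
#'
#' With two modules of periods `lambda1 >= lambda2`, each module's likelihood
#' is a periodic comb of modes. The joint estimate stays on the correct mode
#' only while the displacement between the per-module estimates is below
#' `delta* = min over (n1, n2) != (0, 0) of |n1*lambda1 - n2*lambda2| / 2`,
#' with mode indices `n_i` in `{-K_i, ..., K_i}`, `K_i = ceiling(1/(2 lambda_i))`
#' (the stimulus is assumed mid-domain). For `lambda1 = 1` every `n1 != 0` is
#' one full wrap of the domain, so the search is restricted to
#' `lambda_i * |n_i| < 1`. When both modules are single-peaked no competing
#' mode pair exists and the domain maximum 1/2 is returned by convention.
#'
#' @param lambda1,lambda2 module spatial periods, `0 < lambda2 <= lambda1 <= 1`.
#' @return `delta*` in stimulus units (0 for an ambiguous pair).
#' @export
#' @examples
#' delta_star(1, 0.7)    # 0.35
#' delta_star(0.5, 0.35) # 0.075
delta_star <- function(lambda1, lambda2) {
  stopifnot(lambda2 > 0, lambda2 <= lambda1, lambda1 <= 1)
  restricted <- abs(lambda1 - 1) < 1e-12
  K1 <- ceiling(1 / (2 * lambda1))
  K2 <- ceiling(1 / (2 * lambda2))
  n1 <- -K1:K1
  n2 <- -K2:K2
  if (restricted) {
    n1 <- n1[lambda1 * abs(n1) < 1]
    n2 <- n2[lambda2 * abs(n2) < 1]
  }
  g <- expand.grid(n1 = n1, n2 = n2)
  g <- g[!(g$n1 == 0 & g$n2 == 0), , drop = FALSE]
  if (nrow(g) == 0) return(0.5)
  min(abs(g$n1 * lambda1 - g$n2 * lambda2)) / 2
}

#' Time-normalized Fisher information of one module
#'
#' Restricts the population to the neurons of module `module` and evaluates
#' the closed-form Fisher information at `T = 1` s (using the module's mean
#' amplitude), giving the per-second information the module contributes.
#'
#' @param pop a `neural_population` with `b = 0`.
#' @param module module index in `1..L`.
#' @return scalar `J_norm` in (unit stimulus)^-2 per second.
#' @export
module_fisher_norm <- function(pop, module) {
  stopifnot(module >= 1, module <= pop$layout$L)
  keep <- pop$module == module
  sub <- pop
  sub$N <- sum(keep)
  sub$a <- pop$a[keep]
  sub$lambda <- pop$lambda[keep]
  sub$module <- rep(1L, sub$N)
  sub$prefs <- pop$prefs[keep, , drop = FALSE]
  sub$layout <- list(lambda1 = pop$layout$periods[module], c = 1, L = 1L,
                     M = sub$N, periods = pop$layout$periods[module])
  analytic_fisher(sub, T = 1)
}

#' Lower bound on the minimal decoding time of a two-module population
#'
#' Treating the per-module ML estimates as independent Gaussians with
#' variances `1/(T J_k,norm)`, the probability that their displacement
#' exceeds [delta_star()] is held below `p_error`, which yields
#' `T_th > 2 * (erfinv(1 - p_error) / delta*)^2 * (1/J1_norm + 1/J2_norm)`.
#'
#' @param lambda1,lambda2 module periods.
#' @param J1_norm,J2_norm time-normalized per-module Fisher informations.
#' @param p_error catastrophe probability budget, in `(0, 1)`.
#' @param dstar optional precomputed `delta*`.
#' @return bound in seconds (`Inf` when `delta* = 0`).
#' @export
t_th_two_module <- function(lambda1, lambda2, J1_norm, J2_norm,
                            p_error = 1e-4, dstar = NULL) {
  stopifnot(J1_norm > 0, J2_norm > 0, p_error > 0, p_error < 1)
  if (is.null(dstar)) dstar <- delta_star(lambda1, lambda2)
  if (dstar <= 0) return(Inf)
  erfinv <- qnorm((1 + (1 - p_error)) / 2) / sqrt(2)
  2 * (erfinv / dstar)^2 * (1 / J1_norm + 1 / J2_norm)
}
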