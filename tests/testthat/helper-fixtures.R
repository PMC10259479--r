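# Shared fixtures and memoised heavy computations.
# Small populations are rebuilt cheaply; the grid studies used by the
# acceptance tests are computed once per test run and cached here.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# A small single-peaked population for fast decoder/Fisher tests.
small_pop <- function(N = 100, D = 1, b = 0, seed = 42) {
  build_population(N, D = D, lambda1 = 1, c = 1, L = 1, w = 0.3, b = b,
                   seed = seed)
}

# Reference-scale population (N = 600) used by the anchor checks.
anchor_pop <- function(b = 2, D = 1) {
  build_population(600, D = D, lambda1 = 1, c = 1, L = 1, w = 0.3, b = b,
                   seed = 42)
}

# Scaled-down grid profiles for the acceptance studies (see the methods
# vignette for the choice of problem sizes).
test_profile <- function(n_trials = 1500) {
  mdt_profile("ci", n_trials = n_trials)
}

two_module_study_1 <- function() {
  cached("tm1", run_two_module_study(
    1, c(0.05, 0.15, 0.3, 0.5, 0.7, 0.9),
    profile = test_profile(), seed = 201))
}

two_module_study_half <- function() {
  cached("tmh", run_two_module_study(
    0.5, c(0.28, 0.38, 0.45, 0.55, 0.65, 0.72, 0.85),
    profile = test_profile(), seed = 202))
}

five_module_study <- function(D, b) {
  cgrid <- if (D == 1) c(0.3, 0.45, 0.6, 0.75, 0.9, 1.0) else
    seq(0.3, 1, by = 0.1)
  n <- if (D == 1) 1000 else 1500
  cached(sprintf("fm_%d_%d", D, b), run_five_module_study(
    1, cgrid, D = D, b = b,
    profile = test_profile(n), seed = 300L + D * 10L + b))
}

snn_step_study <- function(n_trials = 30) {
  cached("snn_step", run_snn_study("step", n_trials = n_trials,
                                   duration = 0.8, t_switch = 0.3,
                                   seed = 501))
}

snn_ou_study <- function(n_trials = 30) {
  cached("snn_ou", run_snn_study("ou", n_trials = n_trials, duration = 1.2,
                                 seed = 502))
}

# Independent brute-force enumeration of the maximal tolerable two-module
# displacement (plain loops, used as oracle for delta_star()).
delta_star_brute <- function(l1, l2) {
  K1 <- ceiling(1 / (2 * l1))
  K2 <- ceiling(1 / (2 * l2))
  best <- Inf
  for (n1 in seq(-K1, K1)) {
    for (n2 in seq(-K2, K2)) {
      if (n1 == 0 && n2 == 0) next
      if (abs(l1 - 1) < 1e-12 && (l1 * abs(n1) >= 1 || l2 * abs(n2) >= 1)) next
      best <- min(best, abs(n1 * l1 - n2 * l2) / 2)
    }
  }
  if (!is.finite(best)) 0.5 else best
}

# Siegert (diffusion) firing rate of an LIF neuron with Poisson drive.
# The integrand exp(u^2) * (1 + erf(u)) = 2 exp(u^2) * pnorm(u sqrt(2)) is
# evaluated in log space, where it stays finite for u << 0.
siegert_rate <- function(nu_in, J, tau_m, V_th, V_reset, tau_rp) {
  mu <- J * nu_in * tau_m
  sigma <- J * sqrt(nu_in * tau_m / 2)
  f <- function(u) {
    # log-space evaluation keeps the product finite for u << 0
    exp(u^2 + log(2) + pnorm(u * sqrt(2), log.p = TRUE))
  }
  lo <- (V_reset - mu) / sigma
  hi <- (V_th - mu) / sigma
  I <- integrate(f, lo, hi, rel.tol = 1e-8, subdivisions = 1000L)$value
  1 / (tau_rp + tau_m * sqrt(pi) * I)
}

erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1
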