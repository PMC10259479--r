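test_that("module periods follow a geometric progression and reject ambiguous codes", {
  expect_equal(module_periods(1, 0.7, 2), c(1, 0.7))
  expect_equal(module_periods(1, 1, 5), rep(1, 5))
  expect_equal(module_periods(0.8, 0.5, 3), 0.8 * c(1, 0.5, 0.25))
  # lambda1 = 1/2 with commensurate scale factors cannot span the domain
  expect_error(module_periods(0.5, 0.5, 2), "ambiguous")
  expect_error(module_periods(0.5, 1 / 3, 2), "ambiguous")
  expect_error(module_periods(0.5, 1, 2), "ambiguous")
  expect_silent(module_periods(0.5, 0.7, 2))
})

test_that("tuning rate matches closed-form values at the peak, antipode and on average", {
  p <- tuning_params(a = 10, w = 0.17, lambda = 0.43, pref = 0.31, b = 2)
  expect_equal(tuning_rate(p, 0.31), 12)
  p2 <- tuning_params(a = 20, w = 0.3, lambda = 0.6, pref = 0.2, b = 0)
  expect_equal(tuning_rate(p2, 0.2 + 0.3), 20 * exp(-2 / 0.3), tolerance = 1e-12)
  # mean over the domain for an integer number of peaks: a * exp(-1/w) * B0(1/w)
  p3 <- tuning_params(a = 20, w = 0.3, lambda = 0.25, pref = 0.13, b = 0)
  m <- integrate(function(s) tuning_rate(p3, matrix(s, ncol = 1)), 0, 1,
                 rel.tol = 1e-10)$value
  expect_equal(m, 20 * exp(-1 / 0.3) * besselI(1 / 0.3, 0), tolerance = 1e-8)
})

test_that("tuning rate is periodic in lambda, translation invariant, and bounded", {
  set.seed(7)
  for (k in 1:20) {
    lam <- runif(1, 0.2, 1)
    p <- tuning_params(a = runif(1, 5, 30), w = runif(1, 0.1, 0.6),
                       lambda = lam, pref = runif(1), b = runif(1, 0, 3))
    s <- runif(1)
    expect_equal(tuning_rate(p, s), tuning_rate(p, s + lam), tolerance = 1e-12)
    # joint shift of stimulus and preferred location (no wrap: wrapping only
    # commutes with the shift when 1/lambda is an integer)
    d <- runif(1, 0, 0.99 - max(s, p$pref))
    p_shift <- tuning_params(p$a, p$w, p$lambda, p$pref + d, p$b)
    expect_equal(tuning_rate(p, s), tuning_rate(p_shift, s + d),
                 tolerance = 1e-9)
    r <- tuning_rate(p, matrix(runif(50), ncol = 1))
    expect_true(all(r >= p$b - 1e-12 & r <= p$a + p$b + 1e-12))
  }
})

test_that("amplitude normalization equalizes mean evoked rates", {
  # all integer numbers of peaks: closed-form amplitude
  pop <- build_population(60, D = 1, lambda1 = 1, c = 0.5, L = 2, w = 0.3,
                          seed = 3, fbar_stim = 20 * exp(-1 / 0.3) * besselI(1 / 0.3, 0))
  expect_equal(pop$a, rep(20, 60), tolerance = 1e-8)
  # mixed non-integer periods: quadrature per neuron, amplitudes differ by
  # module but mean evoked rates agree to 1e-6 relative
  pop2 <- build_population(50, D = 1, lambda1 = 1, c = 0.7, L = 5, w = 0.3,
                           seed = 4)
  rates <- evoked_mean_rates(pop2)
  expect_lt(max(abs(rates / pop2$fbar_stim - 1)), 1e-6)
  amp_by_mod <- tapply(pop2$a, pop2$module, mean)
  expect_gt(diff(range(amp_by_mod)), 1e-3)
  # single neuron, lambda = 1
  pop3 <- build_population(1, D = 1, lambda1 = 1, c = 1, L = 1, w = 0.3, seed = 5)
  expect_equal(pop3$a, pop3$fbar_stim / (exp(-1 / 0.3) * besselI(1 / 0.3, 0)),
               tolerance = 1e-9)
})

test_that("multi-dimensional mean evoked rate separates across dimensions", {
  pop <- build_population(10, D = 2, lambda1 = 0.5, c = 1, L = 1, w = 0.3,
                          seed = 6, normalize = FALSE, amplitude = 20)
  m1 <- exp(-1 / 0.3) * besselI(1 / 0.3, 0)
  expect_equal(evoked_mean_rates(pop), rep(20 * m1^2, 10), tolerance = 1e-8)
})

test_that("preferred locations are uniform, reproducible, and in range", {
  x <- sample_preferred_locations(10000, 2, seed = 11)
  expect_true(all(x >= 0 & x < 1))
  expect_identical(x, sample_preferred_locations(10000, 2, seed = 11))
  for (j in 1:2) {
    expect_gt(suppressWarnings(ks.test(x[, j], "punif"))$p.value, 0.01)
  }
})

test_that("populations serialize to JSON and back without change", {
  pop <- build_population(20, D = 2, lambda1 = 1, c = 0.6, L = 2, w = 0.3,
                          b = 1, seed = 9)
  path <- tempfile(fileext = ".json")
  population_to_json(pop, path)
  pop2 <- population_from_json(path)
  expect_equal(pop2$a, pop$a, tolerance = 1e-12)
  expect_equal(pop2$prefs, pop$prefs, tolerance = 1e-12)
  s <- c(0.3, 0.8)
  expect_equal(population_rates(pop2, s), population_rates(pop, s))
})
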