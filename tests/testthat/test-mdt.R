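test_that("MSE estimation is reproducible and asymptotically efficient", {
  pop <- small_pop(N = 100)
  a <- estimate_mse(pop, T = 0.02, n_trials = 200, seed = 3)
  b <- estimate_mse(pop, T = 0.02, n_trials = 200, seed = 3)
  expect_identical(a$mse, b$mse)
  # long windows: the ML decoder reaches the Cramer-Rao floor
  fi <- empirical_fisher(pop, n_stimuli = 5000, seed = 1)
  m <- estimate_mse(pop, T = 5, n_trials = 400, seed = 4)
  expect_lte(mean(m$mse), 1.05 * cr_floor(fi, T = 5))
})

test_that("stability and fixed-n sampling protocols agree", {
  pop <- small_pop(N = 100)
  st <- estimate_mse(pop, T = 0.05, protocol = "stability", seed = 6,
                     return_errors = TRUE)
  fx <- estimate_mse(pop, T = 0.05, protocol = "fixed_n", n_trials = 3000,
                     seed = 7, return_errors = TRUE)
  se <- sqrt(sd(rowMeans(st$eps2))^2 / st$n_trials +
               sd(rowMeans(fx$eps2))^2 / fx$n_trials)
  expect_lt(abs(mean(st$mse) - mean(fx$mse)), 3 * se)
  expect_gte(st$n_trials, 1000)
})

test_that("the stability protocol errors past its trial cap with a partial result", {
  pop <- small_pop(N = 100)
  cnd <- tryCatch(
    estimate_mse(pop, T = 0.001, protocol = "stability", max_trials = 600,
                 seed = 8),
    decodetime_stability_cap = function(e) e)
  expect_s3_class(cnd, "decodetime_stability_cap")
  expect_true(is.numeric(cnd$partial$mse))
})

test_that("a looser threshold factor never increases the minimal decoding time", {
  pop <- small_pop(N = 150)
  common <- list(seed = 21, t_max_ms = 100, scan = "bracket", n_fisher = 3000)
  m2 <- do.call(minimal_decoding_time,
                c(list(pop, mdt_criterion(alpha = 2, n_trials = 400)), common))
  m12 <- do.call(minimal_decoding_time,
                 c(list(pop, mdt_criterion(alpha = 1.2, n_trials = 400)), common))
  expect_gte(m12$T_th_ms, m2$T_th_ms)
  # the returned threshold satisfies the criterion and its predecessor fails
  tr <- m2$trace
  expect_true(tr$predicate[tr$T_ms == m2$T_th_ms])
  if ((m2$T_th_ms - 1) %in% tr$T_ms) {
    expect_false(tr$predicate[tr$T_ms == m2$T_th_ms - 1])
  }
})

test_that("linear and bracketed scans find consistent criterion crossings", {
  pop <- small_pop(N = 150)
  lin <- minimal_decoding_time(pop, mdt_criterion(alpha = 2, n_trials = 300),
                               seed = 31, t_max_ms = 50, scan = "linear",
                               n_fisher = 3000)
  brk <- minimal_decoding_time(pop, mdt_criterion(alpha = 2, n_trials = 300),
                               seed = 31, t_max_ms = 50, scan = "bracket",
                               n_fisher = 3000)
  # per-decoding-time decisions share seeds, so the linear scan's threshold
  # is the first crossing and the bracketed one can only sit at or above it
  expect_gte(brk$T_th_ms, lin$T_th_ms)
  for (res in list(lin, brk)) {
    tr <- res$trace
    expect_true(tr$predicate[tr$T_ms == res$T_th_ms])
    if ((res$T_th_ms - 1) %in% tr$T_ms) {
      expect_false(tr$predicate[tr$T_ms == res$T_th_ms - 1])
    }
  }
})

test_that("a scan that cannot satisfy the criterion reports a capped result", {
  pop <- build_population(600, D = 2, lambda1 = 1, c = 0.5, L = 5, w = 0.3,
                          b = 2, seed = 13)
  res <- minimal_decoding_time(pop, mdt_criterion(alpha = 2, n_trials = 200),
                               seed = 5, t_max_ms = 4, scan = "bracket",
                               n_fisher = 2000)
  expect_true(res$capped)
  expect_true(is.na(res$T_th_ms))
})

test_that("the sequential KS criterion runs and stops at a valid threshold", {
  pop <- small_pop(N = 150)
  ks <- minimal_decoding_time(pop,
                              mdt_criterion("ks_test", n_trials = 400),
                              seed = 41, t_max_ms = 60, n_fisher = 3000)
  expect_false(ks$capped)
  expect_true(all(c("p_value", "level") %in% names(ks$trace)))
  tr <- ks$trace
  expect_true(tr$predicate[tr$T_ms == ks$T_th_ms])
  expect_true(all(!tr$predicate[tr$T_ms < ks$T_th_ms]))
})

test_that("error percentiles pool dimensions and match their definitions", {
  expect_equal(unname(error_percentiles(rep(0, 50))), c(0, 0))
  set.seed(2)
  x <- abs(rnorm(500))
  expect_equal(unname(error_percentiles(x)[2]), max(x))
  m <- matrix(runif(100, 0, 0.25), ncol = 2)
  expect_equal(unname(error_percentiles(m)[2]), max(sqrt(m)))
  expect_error(error_percentiles(numeric(0)))
})
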