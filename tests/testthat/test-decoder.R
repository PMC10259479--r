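test_that("log-likelihood is additive over neurons and exact for r = 0", {
  pop <- build_population(40, D = 1, lambda1 = 1, c = 0.5, L = 2, w = 0.3,
                          seed = 2, normalize = FALSE, amplitude = 20)
  sub1 <- sub2 <- pop
  keep1 <- 1:20; keep2 <- 21:40
  for (fld in c("a", "lambda")) {
    sub1[[fld]] <- pop[[fld]][keep1]
    sub2[[fld]] <- pop[[fld]][keep2]
  }
  sub1$prefs <- pop$prefs[keep1, , drop = FALSE]
  sub2$prefs <- pop$prefs[keep2, , drop = FALSE]
  sub1$module <- pop$module[keep1]; sub2$module <- pop$module[keep2] - 1L
  sub1$N <- sub2$N <- 20
  sub1$layout <- list(lambda1 = 1, c = 1, L = 1, M = 20, periods = 1)
  sub2$layout <- list(lambda1 = 0.5, c = 1, L = 1, M = 20, periods = 0.5)
  set.seed(5)
  r <- rpois(40, 2)
  s <- 0.42; T <- 0.1
  expect_equal(log_likelihood(r, s, pop, T),
               log_likelihood(r[keep1], s, sub1, T) +
                 log_likelihood(r[keep2], s, sub2, T),
               tolerance = 1e-10)
  expect_equal(log_likelihood(rep(0, 40), s, pop, T),
               -T * sum(population_rates(pop, s)), tolerance = 1e-10)
})

test_that("log-likelihood differs from the full Poisson log-pmf by a constant in s", {
  pop <- small_pop(N = 30)
  T <- 0.3
  set.seed(8)
  for (k in 1:5) {
    s0 <- runif(1)
    r <- sample_spike_counts(pop, s0, T, seed = k)$counts
    ss <- runif(4)
    diffs <- vapply(ss, function(s) {
      log_likelihood(r, s, pop, T) -
        sum(dpois(r, T * population_rates(pop, s), log = TRUE))
    }, numeric(1))
    expect_equal(diffs, rep(sum(lgamma(r + 1)), 4), tolerance = 1e-8)
  }
})

test_that("circular error handles wrapping, identity, and the antipode", {
  expect_equal(wrap_unit(1.1), 0.1)
  expect_equal(circular_error(0.95, 0.05), 0.01)
  expect_equal(circular_error(0.4, 0.4), 0)
  expect_equal(circular_error(0, 0.5), 0.25)
  # invariant under argument exchange
  set.seed(3)
  a <- runif(20); b <- runif(20)
  expect_equal(circular_error(a, b), circular_error(b, a))
  expect_true(all(circular_error(a, b) <= 0.25))
})

test_that("ML decoding matches a dense-grid search of the likelihood", {
  pop <- build_population(200, D = 1, lambda1 = 1, c = 0.7, L = 2, w = 0.3,
                          seed = 21)
  T <- 0.05
  grid <- matrix(seq(0, 1 - 1e-4, by = 1e-4), ncol = 1)
  set.seed(99)
  for (k in 1:60) {
    s0 <- runif(1)
    obs <- sample_spike_counts(pop, s0, T)
    d <- decode_ml(obs$counts, pop, T, s_true = s0)
    vg <- loglik_grid_cpp(decodetime:::pop_pack(pop), obs$counts, grid, T)
    expect_gte(d$log_likelihood, max(vg) - 1e-5)
    expect_true(all(d$s_ml >= 0 & d$s_ml < 1))
  }
})

test_that("the ML decoder is consistent in the long-window limit", {
  pop <- anchor_pop(b = 2)
  est <- estimate_mse(pop, T = 10, n_trials = 100, seed = 4,
                      return_errors = TRUE)
  err <- sqrt(est$eps2[, 1])
  expect_gte(mean(err < 0.01), 0.99)
})

test_that("decoding is equivariant under circular translation", {
  pop <- build_population(80, D = 1, lambda1 = 1, c = 0.5, L = 2, w = 0.3,
                          seed = 6)
  delta <- 0.3173
  pop_shift <- pop
  pop_shift$prefs <- (pop$prefs + delta) %% 1
  cand <- matrix(seq(0.005, 0.995, length.out = 100), ncol = 1)
  set.seed(44)
  for (k in 1:5) {
    s0 <- runif(1)
    r <- sample_spike_counts(pop, s0, 0.05, seed = 100 + k)$counts
    d0 <- decode_ml(r, pop, 0.05, s_true = s0, candidates = cand)
    d1 <- decode_ml(r, pop_shift, 0.05, s_true = wrap_unit(s0 + delta),
                    candidates = wrap_unit(cand + delta))
    expect_lt(circular_distance(wrap_unit(d0$s_ml + delta), d1$s_ml), 1e-4)
  }
})

test_that("discarding trials with out-of-domain pre-wrap optima leaves the MSE unchanged", {
  pop <- small_pop(N = 100)
  T <- 0.01
  set.seed(17)
  eps2 <- numeric(0)
  outside <- logical(0)
  for (k in 1:400) {
    s0 <- runif(1)
    obs <- sample_spike_counts(pop, s0, T)
    d <- decode_ml(obs$counts, pop, T, s_true = s0)
    eps2 <- c(eps2, d$eps2)
    outside <- c(outside, any(d$s_prewrap < 0 | d$s_prewrap >= 1))
  }
  if (sum(!outside) > 10 && sum(outside) > 0) {
    m_all <- mean(eps2)
    m_in <- mean(eps2[!outside])
    se <- sd(eps2) / sqrt(sum(!outside))
    expect_lt(abs(m_all - m_in), 3 * se + 1e-8)
  } else {
    succeed("too few out-of-domain optima to compare")
  }
})
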