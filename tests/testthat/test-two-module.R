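test_that("delta* matches hand-computed cases and conventions", {
  expect_equal(delta_star(1, 0.7), 0.35)
  expect_equal(delta_star(0.5, 0.35), 0.075)
  expect_equal(delta_star(0.6, 0.6), 0)   # ambiguous pair
  expect_equal(delta_star(1, 1), 0.5)     # both single-peaked: no competitor
})

test_that("delta* agrees with brute-force enumeration on random period pairs", {
  set.seed(12)
  for (k in 1:200) {
    l1 <- if (k %% 3 == 0) 1 else runif(1, 0.15, 1)
    l2 <- runif(1, 0.05, l1)
    expect_equal(delta_star(l1, l2), delta_star_brute(l1, l2),
                 info = sprintf("l1=%g l2=%g", l1, l2))
  }
})

test_that("delta* dips where the mode structure predicts catastrophes", {
  # lambda1 = 1: the restricted search means only small scale factors are
  # dangerous; near c = 1 the competing mode is half a period away
  expect_gt(delta_star(1, 0.7), 0.3)
  expect_lt(delta_star(1, 0.05), 0.03)
  expect_equal(delta_star(1, 0.999), 0.999 / 2)
  # lambda1 < 1: near-equal periods and near-rational ratios are dangerous
  expect_lt(delta_star(0.9, 0.899), 0.01)
  expect_lt(delta_star(0.9, 0.451), 0.01)
  expect_gt(delta_star(0.9, 0.6), 0.1)
})

test_that("the two-module bound scales as stated in its inputs", {
  base <- t_th_two_module(1, 0.7, 2e5, 3e5)
  expect_equal(t_th_two_module(1, 0.7, 2e5, 3e5, dstar = 0.175), 4 * base)
  expect_equal(t_th_two_module(1, 0.7, 4e5, 6e5), base / 2)
  expect_identical(t_th_two_module(0.6, 0.6, 1e5, 1e5), Inf)
})

test_that("per-module Fisher information matches restriction and scaling laws", {
  pop <- build_population(200, D = 1, lambda1 = 1, c = 1, L = 2, w = 0.3,
                          seed = 31)
  expect_equal(module_fisher_norm(pop, 1), module_fisher_norm(pop, 2))
  pop2 <- build_population(200, D = 1, lambda1 = 1, c = 0.5, L = 2, w = 0.3,
                           seed = 31, normalize = FALSE, amplitude = 20)
  expect_equal(module_fisher_norm(pop2, 2) / module_fisher_norm(pop2, 1),
               0.5^-2, tolerance = 1e-12)
  # Monte-Carlo cross-check on the restricted subpopulation
  sub <- build_population(100, D = 1, lambda1 = 0.5, c = 1, L = 1, w = 0.3,
                          prefs = pop2$prefs[101:200, , drop = FALSE],
                          normalize = FALSE, amplitude = 20)
  emp <- empirical_fisher(sub, n_stimuli = 20000, seed = 3)$J[1, 1]
  expect_equal(emp, module_fisher_norm(pop2, 2), tolerance = 0.01)
})

test_that("delta* rescales linearly with a common period scaling", {
  set.seed(5)
  for (k in 1:20) {
    l1 <- runif(1, 0.3, 0.9)
    l2 <- runif(1, 0.1, l1)
    kf <- runif(1, 0.5, 1)
    # keep the enumeration ranges identical by comparing against the scaled
    # brute force with the same index caps
    K1 <- ceiling(1 / (2 * l1)); K2 <- ceiling(1 / (2 * l2))
    brute_fixed <- function(a, b) {
      best <- Inf
      for (n1 in -K1:K1) for (n2 in -K2:K2) {
        if (n1 == 0 && n2 == 0) next
        best <- min(best, abs(n1 * a - n2 * b) / 2)
      }
      best
    }
    expect_equal(brute_fixed(kf * l1, kf * l2), kf * brute_fixed(l1, l2),
                 tolerance = 1e-12)
  }
})
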