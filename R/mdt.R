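#' Minimal-decoding-time criterion
#'
#' Two stopping rules are supported while scanning the decoding time upward in
#' 1 ms steps. `"mse_threshold"`: stop at the first `T` where the
#' dimension-averaged empirical MSE is at most `alpha` times the
#' dimension-averaged Cramer-Rao floor `diag(J(T)^-1)`. `"ks_test"`: stop at
#' the first `T` where a one-sided Kolmogorov-Smirnov test no longer rejects
#' (at sequential Bonferroni level `sig_level / j` for the j-th comparison)
#' that the standardized errors are at least as concentrated as the Gaussian
#' law `N(0, J^-1)` implied by the bound.
#'
#' @param kind `"mse_threshold"` or `"ks_test"`.
#' @param alpha threshold factor (>= 1) relaxing the bound, e.g. 2 or 1.2.
#' @param sig_level KS significance level before the sequential correction.
#' @param protocol `"fixed_n"` (a fixed trial count per `T`) or `"stability"`
#'   (sample until the two leading digits of the MSE stabilize).
#' @param n_trials trials per decoding time under `"fixed_n"`.
#' @return an `mdt_criterion` list.
#' @export
mdt_criterion <- function(kind = c("mse_threshold", "ks_test"), alpha = 2,
                          sig_level = 0.05,
                          protocol = c("fixed_n", "stability"),
                          n_trials = 15000) {
  kind <- match.arg(kind)
  protocol <- match.arg(protocol)
  stopifnot(alpha >= 1, sig_level > 0, sig_level < 1, n_trials >= 1)
  structure(list(kind = kind, alpha = alpha, sig_level = sig_level,
                 protocol = protocol, n_trials = n_trials),
            class = "mdt_criterion")
}

#' Empirical MSE of the ML decoder at a fixed decoding time
#'
#' Repeatedly samples a uniform stimulus, Poisson counts over the window `T`,
#' decodes by maximum likelihood and averages the squared circular errors.
#' Under the `"stability"` protocol trials accumulate until the two leading
#' non-zero digits of the dimension-averaged MSE are unchanged over 1000
#' consecutive trials (hard cap `max_trials`, exceeding it raises an error
#' carrying the partial result).
#'
#' @param pop a `neural_population`.
#' @param T decoding time in seconds.
#' @param protocol `"fixed_n"` or `"stability"`.
#' @param n_trials trial count for `"fixed_n"`.
#' @param seed optional integer seed.
#' @param return_errors also return the per-trial squared-error matrix.
#' @param max_trials hard cap for the stability protocol.
#' @param n_candidates,ptol,ftol,maxit decoder settings (see [decode_ml()]).
#' @return list with per-dimension `mse`, `n_trials`, mean total `spikes`
#'   per trial, and optionally `eps2` (`n x D`).
#' @export
estimate_mse <- function(pop, T, protocol = c("fixed_n", "stability"),
                         n_trials = 15000, seed = NULL, return_errors = FALSE,
                         max_trials = 1e6, n_candidates = 100,
                         ptol = 1e-6, ftol = 1e-8, maxit = 2000) {
  protocol <- match.arg(protocol)
  stopifnot(T > 0)
  pack <- pop_pack(pop)
  run <- function() {
    if (protocol == "fixed_n") {
      out <- mse_trials_cpp(pack, T, as.integer(n_trials),
                            as.integer(n_candidates), ptol, ftol,
                            as.integer(maxit))
      list(eps2 = out$eps2, spikes = out$spikes)
    } else {
      eps2 <- NULL
      spikes <- numeric(0)
      batch <- 200L
      repeat {
        out <- mse_trials_cpp(pack, T, batch, as.integer(n_candidates),
                              ptol, ftol, as.integer(maxit))
        eps2 <- rbind(eps2, out$eps2)
        spikes <- c(spikes, out$spikes)
        n <- nrow(eps2)
        if (n >= 1000) {
          running <- cumsum(rowMeans(eps2)) / seq_len(n)
          r <- signif(running, 2)
          if (all(r[(n - 999):n] == r[n])) break
        }
        if (n >= max_trials) {
          stop(errorCondition(
            sprintf("stability protocol exceeded the %d-trial cap", max_trials),
            partial = list(mse = colMeans(eps2), n_trials = n),
            class = c("decodetime_stability_cap", "error")))
        }
      }
      list(eps2 = eps2, spikes = spikes)
    }
  }
  out <- with_seed(seed, run())
  res <- list(mse = colMeans(out$eps2), n_trials = nrow(out$eps2),
              spikes = mean(out$spikes), T = T, protocol = protocol)
  if (return_errors) res$eps2 <- out$eps2
  res
}

#' Evaluate the MSE-threshold predicate at one decoding time
#'
#' Computes the dimension-averaged MSE over `n_trials` decoding trials at
#' `T_ms` milliseconds and compares it with `alpha` times the
#' dimension-averaged Cramer-Rao floor from the Monte-Carlo Fisher matrix.
#'
#' @param pop a `neural_population`.
#' @param T_ms decoding time in ms.
#' @param alpha threshold factor.
#' @param n_trials trials to use.
#' @param seed optional integer seed.
#' @param fisher optional precomputed `fisher_matrix` (time-normalized).
#' @param n_fisher Monte-Carlo stimuli if `fisher` is missing.
#' @return list with `mse`, `floor`, logical `predicate`, `se` of the MSE.
#' @export
mdt_predicate <- function(pop, T_ms, alpha = 2, n_trials = 1500, seed = NULL,
                          fisher = NULL, n_fisher = 10000) {
  if (is.null(fisher)) {
    fisher <- empirical_fisher(pop, T = 1, n_stimuli = n_fisher,
                               seed = if (is.null(seed)) NULL
                                      else derive_seed(seed, "fisher"))
  }
  T_s <- T_ms / 1000
  floor_bar <- cr_floor(fisher, T = T_s)
  est <- estimate_mse(pop, T_s, protocol = "fixed_n", n_trials = n_trials,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, "mse", T_ms),
                      return_errors = TRUE)
  davg <- rowMeans(est$eps2)
  list(mse = mean(est$mse), floor = floor_bar,
       predicate = mean(est$mse) <= alpha * floor_bar,
       se = sd(davg) / sqrt(length(davg)), n_trials = est$n_trials)
}

# One predicate decision with optional early stopping: clear failures
# (MSE far above the threshold) are declared after a fraction of the trial
# budget, but a PASS always consumes the full budget, since passing hinges on
# the rare-event tail of the error distribution.
decide_mse_predicate <- function(pack, T_ms, alpha, floor_norm, n_trials,
                                 seed, adaptive, min_batch = 250,
                                 decide_z = 4) {
  T_s <- T_ms / 1000
  thr <- alpha * floor_norm / T_s
  set.seed(seed)
  if (!adaptive) {
    out <- mse_trials_cpp(pack, T_s, as.integer(n_trials), 100L, 1e-6, 1e-8, 2000L)
    davg <- rowMeans(out$eps2)
    return(list(mse = mean(davg), predicate = mean(davg) <= thr,
                n = n_trials, floor = floor_norm / T_s))
  }
  davg <- numeric(0)
  repeat {
    m <- min(min_batch, n_trials - length(davg))
    out <- mse_trials_cpp(pack, T_s, as.integer(m), 100L, 1e-6, 1e-8, 2000L)
    davg <- c(davg, rowMeans(out$eps2))
    n <- length(davg)
    mse <- mean(davg)
    if (n >= n_trials) {
      return(list(mse = mse, predicate = mse <= thr, n = n,
                  floor = floor_norm / T_s))
    }
    se <- sd(davg) / sqrt(n)
    if (mse - thr > decide_z * se) {
      return(list(mse = mse, predicate = FALSE, n = n,
                  floor = floor_norm / T_s))
    }
  }
}

#' Minimal decoding time of a population
#'
#' Scans the decoding time upward on a 1 ms grid and returns the first time at
#' which the chosen criterion holds; at `T_th - 1` ms it does not. The
#' Cramer-Rao floor uses the Monte-Carlo Fisher matrix (exact for any
#' baseline, and in agreement with the closed form when `b = 0`).
#'
#' Two scan strategies are available. `"linear"` evaluates every millisecond
#' with the full trial budget, as in the reference protocol. `"bracket"`
#' doubles the decoding time until the criterion first holds and then
#' bisects, so only O(log T_th) decoding times are evaluated and clear
#' failures stop early; each decoding time uses its own derived seed, so the
#' bracketing path does not change any individual decision.
#'
#' @param pop a `neural_population`.
#' @param criterion an [mdt_criterion()].
#' @param seed master seed for all trial streams.
#' @param t_max_ms scan cap; if no time satisfies the criterion the result is
#'   flagged `capped` (not an error).
#' @param scan `"linear"` or `"bracket"`.
#' @param fisher optional precomputed time-normalized `fisher_matrix`.
#' @param n_fisher Monte-Carlo stimuli for the Fisher matrix.
#' @return an `mdt_result`: `T_th_ms` (NA when capped), the per-`T` trace of
#'   MSE and floor, the criterion, the Fisher matrix used, and the seed.
#' @export
minimal_decoding_time <- function(pop, criterion = mdt_criterion(),
                                  seed = 1L, t_max_ms = 500,
                                  scan = c("linear", "bracket"),
                                  fisher = NULL, n_fisher = 10000) {
  scan <- match.arg(scan)
  stopifnot(inherits(criterion, "mdt_criterion"))
  if (is.null(fisher)) {
    fisher <- empirical_fisher(pop, T = 1, n_stimuli = n_fisher,
                               seed = derive_seed(seed, "fisher"))
  }
  floor_norm <- cr_floor(fisher, T = 1)
  pack <- pop_pack(pop)
  trace <- list()

  if (criterion$kind == "ks_test") {
    res <- mdt_ks_scan(pop, pack, criterion, seed, t_max_ms, fisher, trace)
    return(res)
  }

  eval_T <- function(T_ms, adaptive, n_mult = 1) {
    if (criterion$protocol == "stability" && !adaptive) {
      est <- estimate_mse(pop, T_ms / 1000, protocol = "stability",
                          seed = derive_seed(seed, "mse", T_ms))
      d <- list(mse = mean(est$mse), floor = floor_norm / (T_ms / 1000),
                n = est$n_trials,
                predicate = mean(est$mse) <=
                  criterion$alpha * floor_norm / (T_ms / 1000))
    } else {
      d <- decide_mse_predicate(pack, T_ms, criterion$alpha, floor_norm,
                                criterion$n_trials * n_mult,
                                seed = derive_seed(seed, "mse", T_ms),
                                adaptive = adaptive)
    }
    trace[[length(trace) + 1]] <<- data.frame(
      T_ms = T_ms, mse = d$mse, cr_floor = d$floor, n_trials = d$n,
      predicate = d$predicate)
    d$predicate
  }

  T_th <- NA_integer_
  capped <- FALSE
  if (scan == "linear") {
    for (T_ms in seq_len(t_max_ms)) {
      if (eval_T(T_ms, adaptive = FALSE)) { T_th <- T_ms; break }
    }
    if (is.na(T_th)) capped <- TRUE
  } else {
    if (eval_T(1L, adaptive = TRUE)) {
      T_th <- 1L
    } else {
      lo <- 1L
      hi <- NA_integer_
      Tc <- 2L
      repeat {
        Tc <- min(Tc, as.integer(t_max_ms))
        if (eval_T(Tc, adaptive = TRUE)) { hi <- Tc; break }
        lo <- Tc
        if (Tc >= t_max_ms) break
        Tc <- Tc * 2L
      }
      if (is.na(hi)) {
        capped <- TRUE
      } else {
        while (hi - lo > 1L) {
          mid <- as.integer((lo + hi) %/% 2)
          # final refinement steps double the trial budget: the decisions
          # that pin down T_th to the millisecond are the noisiest
          mult <- if (hi - lo <= 4L) 2 else 1
          if (eval_T(mid, adaptive = TRUE, n_mult = mult)) hi <- mid
          else lo <- mid
        }
        T_th <- hi
      }
    }
  }
  tr <- do.call(rbind, trace)
  tr <- tr[order(tr$T_ms), , drop = FALSE]
  structure(list(T_th_ms = T_th, capped = capped, trace = tr,
                 criterion = criterion, fisher = fisher, seed = seed,
                 scan = scan),
            class = "mdt_result")
}

# Sequential KS-test criterion: at the j-th decoding time, standardize the
# per-dimension errors by the Cramer-Rao standard deviation, pool dimensions,
# and test |z| against the half-normal law, one-sided in the direction
# "empirical errors stochastically larger => reject"; stop at the first
# decoding time whose test fails to reject at level sig_level / j.
mdt_ks_scan <- function(pop, pack, criterion, seed, t_max_ms, fisher, trace) {
  inv_diag <- diag(solve(fisher$J_norm))
  T_th <- NA_integer_
  capped <- FALSE
  for (j in seq_len(t_max_ms)) {
    T_ms <- j
    T_s <- T_ms / 1000
    set.seed(derive_seed(seed, "mse", T_ms))
    out <- mse_trials_cpp(pack, T_s, as.integer(criterion$n_trials), 100L,
                          1e-6, 1e-8, 2000L)
    sdv <- sqrt(inv_diag / T_s)
    z <- as.numeric(sweep(sqrt(out$eps2), 2, sdv, "/"))
    p <- suppressWarnings(
      ks.test(z, function(q) pmax(0, 2 * pnorm(q) - 1),
              alternative = "less")$p.value)
    level <- criterion$sig_level / j
    trace[[length(trace) + 1]] <- data.frame(
      T_ms = T_ms, mse = mean(colMeans(out$eps2)),
      cr_floor = mean(inv_diag) / T_s, n_trials = criterion$n_trials,
      predicate = p >= level, p_value = p, level = level)
    if (p >= level) { T_th <- T_ms; break }
  }
  if (is.na(T_th)) capped <- TRUE
  structure(list(T_th_ms = T_th, capped = capped,
                 trace = do.call(rbind, trace), criterion = criterion,
                 fisher = fisher, seed = seed, scan = "linear"),
            class = "mdt_result")
}

#' Percentiles of the absolute error distribution
#'
#' Error distributions across stimulus dimensions are pooled; the 100th
#' percentile is the maximal error of the sample.
#'
#' @param errors vector of root squared errors, or an `n x D` matrix of
#'   squared errors (`eps2`) which is pooled and square-rooted.
#' @param percentiles percentiles in `[0, 100]`.
#' @return named numeric vector of percentile values.
#' @export
error_percentiles <- function(errors, percentiles = c(99.8, 100)) {
  if (is.matrix(errors)) errors <- sqrt(as.numeric(errors))
  stopifnot(length(errors) > 0)
  out <- quantile(errors, probs = percentiles / 100, names = FALSE, type = 7)
  names(out) <- paste0("p", percentiles)
  out
}

#' @export
print.mdt_result <- function(x, ...) {
  if (x$capped) {
    cat(sprintf("Minimal decoding time: exceeds the %d ms scan cap\n",
                max(x$trace$T_ms)))
  } else {
    cat(sprintf("Minimal decoding time: %d ms (%s, alpha = %g, %s scan)\n",
                x$T_th_ms, x$criterion$kind, x$criterion$alpha, x$scan))
  }
  invisible(x)
}
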