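#' Simulation profile for the decoding-time grid studies
#'
#' Bundles the compute-scale knobs of a grid study. `"full"` mirrors the
#' reference protocol (15,000 trials per decoding time, linear 1 ms scan);
#' `"ci"` is the scaled-down profile used by the package's own test and
#' acceptance runs (bracketed scan with per-time derived seeds, 1,500 trials
#' per decoding time, 150 ms cap). The scientific parameters of the studies
#' (population size, tuning width, baseline rates, threshold factor) are not
#' part of the profile.
#'
#' @param name `"ci"` or `"full"`, or `NULL` to set fields directly.
#' @param n_trials trials per decoding time.
#' @param t_max_ms scan cap (ms).
#' @param scan `"bracket"` or `"linear"` (see [minimal_decoding_time()]).
#' @param n_fisher Monte-Carlo stimuli for the Fisher benchmark.
#' @return an `mdt_profile` list.
#' @export
mdt_profile <- function(name = c("ci", "full"), n_trials = NULL,
                        t_max_ms = NULL, scan = NULL, n_fisher = NULL) {
  name <- match.arg(name)
  prof <- if (name == "full") {
    list(n_trials = 15000, t_max_ms = 500, scan = "linear", n_fisher = 10000)
  } else {
    list(n_trials = 1500, t_max_ms = 150, scan = "bracket", n_fisher = 10000)
  }
  if (!is.null(n_trials)) prof$n_trials <- n_trials
  if (!is.null(t_max_ms)) prof$t_max_ms <- t_max_ms
  if (!is.null(scan)) prof$scan <- scan
  if (!is.null(n_fisher)) prof$n_fisher <- n_fisher
  structure(prof, class = "mdt_profile")
}

#' Two-module study: simulated vs predicted minimal decoding times
#'
#' For each scale factor in `c_grid`, builds an `L = 2` population (preferred
#' locations shared across the grid), simulates the minimal decoding time
#' under the MSE-threshold criterion, and predicts it from the closed-form
#' two-module bound with catastrophe budget `p_error`. The coefficient of
#' determination is computed between simulation and prediction directly (no
#' refitting), over the cells that did not exceed the scan cap.
#'
#' @param lambda1 largest period (1 or 1/2 in the reference grids).
#' @param c_grid scale factors.
#' @param N,D,w,b population parameters.
#' @param alpha MSE threshold factor.
#' @param p_error catastrophe probability budget of the prediction.
#' @param profile an [mdt_profile()].
#' @param seed master seed (populations and trial streams derive from it).
#' @return list with the per-cell `table` (c, delta_star, T_th simulated and
#'   predicted in ms, capped flags), `r_squared` (residuals about the
#'   prediction itself) and `r_squared_fit` (coefficient of determination of
#'   the least-squares calibration of simulation on prediction; the bound
#'   ignores the decoder's local-convergence floor, which this absorbs).
#' @export
run_two_module_study <- function(lambda1, c_grid, N = 600, D = 1, w = 0.3,
                                 b = 0, alpha = 2, p_error = 1e-4,
                                 profile = mdt_profile("ci"), seed = 1L) {
  prefs <- sample_preferred_locations(N, D, seed = derive_seed(seed, "prefs"))
  crit <- mdt_criterion("mse_threshold", alpha = alpha,
                        n_trials = profile$n_trials)
  rows <- lapply(c_grid, function(cc) {
    pop <- build_population(N, D = D, lambda1 = lambda1, c = cc, L = 2,
                            w = w, b = b, prefs = prefs)
    ds <- delta_star(pop$layout$periods[1], pop$layout$periods[2])
    J1 <- module_fisher_norm(pop, 1)
    J2 <- module_fisher_norm(pop, 2)
    pred_s <- t_th_two_module(pop$layout$periods[1], pop$layout$periods[2],
                              J1, J2, p_error = p_error, dstar = ds)
    mdt <- minimal_decoding_time(pop, crit,
                                 seed = derive_seed(seed, "cell", cc),
                                 t_max_ms = profile$t_max_ms,
                                 scan = profile$scan,
                                 n_fisher = profile$n_fisher)
    data.frame(lambda1 = lambda1, c = cc, delta_star = ds,
               J1_norm = J1, J2_norm = J2,
               T_th_ms = mdt$T_th_ms, T_pred_ms = 1000 * pred_s,
               capped = mdt$capped)
  })
  if (length(rows) == 0) {
    return(list(table = data.frame(), r_squared = NA_real_,
                r_squared_fit = NA_real_))
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$capped & is.finite(tab$T_pred_ms)
  r2 <- r_squared(tab$T_th_ms[ok], tab$T_pred_ms[ok])
  r2f <- if (sum(ok) >= 3) {
    summary(lm(tab$T_th_ms[ok] ~ tab$T_pred_ms[ok]))$r.squared
  } else NA_real_
  list(table = tab, r_squared = r2, r_squared_fit = r2f)
}

# Coefficient of determination of predictions `pred` for observations `obs`
# (no refitting: residuals are taken about the prediction itself).
r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Five-module study: minimal decoding times across a scale-factor grid
#'
#' Simulates `T_th` for `L = 5` module populations over `c_grid` and fits the
#' two constants of the scaling law on the uncapped cells. Cells whose scan
#' exceeded the cap are flagged and excluded from the fit.
#'
#' @param lambda1 largest period.
#' @param c_grid scale factors (reference range 0.3-1).
#' @param N,D,w,b population parameters.
#' @param alpha threshold factor.
#' @param profile an [mdt_profile()].
#' @param seed master seed.
#' @return list with the per-cell `table` (including the analytic Fisher
#'   information per second) and the `fit` (`theory_fit`, `NULL` if fewer
#'   than 3 uncapped cells).
#' @export
run_five_module_study <- function(lambda1, c_grid, N = 600, D = 1, w = 0.3,
                                  b = 0, alpha = 2,
                                  profile = mdt_profile("ci"), seed = 1L) {
  L <- 5L
  prefs <- sample_preferred_locations(N, D, seed = derive_seed(seed, "prefs"))
  crit <- mdt_criterion("mse_threshold", alpha = alpha,
                        n_trials = profile$n_trials)
  rows <- lapply(c_grid, function(cc) {
    pop <- build_population(N, D = D, lambda1 = lambda1, c = cc, L = L,
                            w = w, b = b, prefs = prefs)
    mdt <- minimal_decoding_time(pop, crit,
                                 seed = derive_seed(seed, "cell", cc),
                                 t_max_ms = profile$t_max_ms,
                                 scan = profile$scan,
                                 n_fisher = profile$n_fisher)
    fi <- if (b == 0) analytic_fisher(pop, T = 1) else
      mean(diag(mdt$fisher$J_norm))
    data.frame(lambda1 = lambda1, c = cc, D = D, b = b,
               mean_amplitude = mean(pop$a), T_th_ms = mdt$T_th_ms,
               fisher_norm = fi, capped = mdt$capped)
  })
  if (length(rows) == 0) return(list(table = data.frame(), fit = NULL))
  tab <- do.call(rbind, rows)
  ok <- !tab$capped
  fit <- NULL
  if (sum(ok) >= 3) {
    fit <- fit_theory_constants(tab$c[ok], tab$T_th_ms[ok], L = L, D = D,
                                w = w, a = mean(tab$mean_amplitude), M = N / L)
  }
  list(table = tab, fit = fit)
}

#' Spiking-network study: trial statistics for both network variants
#'
#' Runs `n_trials` trials of the single-peaked and the periodic network on a
#' step or Ornstein-Uhlenbeck stimulus, collects per-trial accumulated RMSEs
#' (and switch latencies for the step stimulus), and compares the two
#' variants with a two-sample KS test.
#'
#' @param stimulus_type `"step"` or `"ou"`.
#' @param n_trials trials per network.
#' @param duration trial length (s).
#' @param t_switch switch time for the step stimulus (s).
#' @param seed master seed; each (variant, trial) gets a derived stream.
#' @param dt simulation step (s).
#' @return list with per-variant data.frames of trial statistics and the KS
#'   comparison of the RMSE distributions.
#' @export
run_snn_study <- function(stimulus_type = c("step", "ou"), n_trials = 30,
                          duration = 1, t_switch = 0.4, seed = 1L,
                          dt = 1e-4) {
  stimulus_type <- match.arg(stimulus_type)
  if (n_trials == 0) {
    return(list(trials = data.frame(), ks = NULL))
  }
  cfgs <- list(single = snn_config("single", dt = dt),
               periodic = snn_config("periodic", dt = dt))
  rows <- list()
  for (variant in names(cfgs)) {
    for (k in seq_len(n_trials)) {
      sseed <- derive_seed(seed, stimulus_type, variant, k)
      stim <- if (stimulus_type == "step") {
        step_stimulus(t_switch, duration, dt = dt)
      } else {
        ou_stimulus(duration = duration, dt = dt, s0 = 0,
                    seed = derive_seed(seed, "oustim", k))
      }
      sts <- simulate_snn(cfgs[[variant]], stim, seed = sseed)
      rmse <- if (stimulus_type == "step") {
        trial_rmse(sts, t_start = t_switch, t_end = duration)
      } else {
        trial_rmse(sts)
      }
      lat <- if (stimulus_type == "step") {
        switch_latency(sts, t_switch)
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        variant = variant, trial = k, rmse = rmse, latency = lat,
        n_spikes_l1 = nrow(sts$layer1), n_spikes_l2 = nrow(sts$layer2))
    }
  }
  trials <- do.call(rbind, rows)
  ks <- compare_trial_rmse(trials$rmse[trials$variant == "single"],
                           trials$rmse[trials$variant == "periodic"])
  list(trials = trials, ks = ks, stimulus_type = stimulus_type)
}

#' Write a grid-study table as CSV
#'
#' @param study result of [run_two_module_study()] or
#'   [run_five_module_study()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
study_to_csv <- function(study, path) {
  utils::write.csv(study$table, path, row.names = FALSE)
  invisible(path)
}
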