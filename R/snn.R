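#' LIF neuron parameters
#'
#' Shared by both layers of the network: membrane time constant 20 ms,
#' threshold 20 mV, reset 10 mV, rest 0 mV, refractory period 2 ms.
#'
#' @param tau_mem membrane time constant (s).
#' @param V_th spike threshold (mV).
#' @param V_reset post-spike reset (mV), below `V_th`.
#' @param V_rest resting potential (mV).
#' @param tau_rp absolute refractory period (s).
#' @return a `lif_params` list.
#' @export
lif_params <- function(tau_mem = 0.020, V_th = 20, V_reset = 10, V_rest = 0,
                       tau_rp = 0.002) {
  stopifnot(tau_mem > 0, tau_rp > 0, V_reset < V_th)
  structure(list(tau_mem = tau_mem, V_th = V_th, V_reset = V_reset,
                 V_rest = V_rest, tau_rp = tau_rp), class = "lif_params")
}

#' Configuration of the two-layer feed-forward spiking network
#'
#' Layer 1 (`N1 = 500` neurons, no recurrent connections) receives Poisson
#' input whose rate is a circular tuning curve of the stimulus: either all
#' single-peaked (`variant = "single"`, period 1) or periodic with four
#' modules of spatial frequencies 1..4, i.e. periods 1, 1/2, 1/3, 1/4
#' (`variant = "periodic"`). Preferred locations are equidistant on
#' `[0, lambda_j)` within each module. Layer 2 (`N2 = 400`) is a readout
#' layer with preferred locations `k / N2`; its feed-forward EPSP from a
#' layer-1 neuron decays with the (smallest, over peaks) circular difference
#' in preferred tuning, with width `w_ro = (pi/N2)^2 / (2 log 2)` chosen so
#' the EPSP kernels' full width at half maximum tiles the domain without
#' overlap. Readout neurons inhibit each other with the broad kernel
#' `-J_I * |sin(pi * delta)|` (winner-take-all dynamics), and also receive
#' non-specific Poisson background drive.
#'
#' @param variant `"single"` or `"periodic"` first-layer tuning.
#' @param N1,N2 layer sizes.
#' @param a_in peak stimulus-evoked input rate (sp/s).
#' @param b_in baseline input rate (sp/s).
#' @param w input tuning width.
#' @param J_E input EPSP (mV).
#' @param J_EE maximal feed-forward EPSP (mV).
#' @param J_I maximal lateral IPSP magnitude (mV).
#' @param delay synaptic delay (s).
#' @param dt simulation step (s), at most 0.1 ms.
#' @param b_ext rate of the non-specific drive to layer 2 (sp/s). The
#'   reference description leaves this rate open; the default 4000 sp/s is
#'   chosen so that background drive alone leaves readout neurons quiescent
#'   (< 1 sp/s) while matched feed-forward input drives them reliably, giving
#'   the intended winner-take-all readout.
#' @param lif a [lif_params()] object.
#' @return an `snn_config` list (includes the precomputed weight matrices).
#' @export
snn_config <- function(variant = c("single", "periodic"), N1 = 500, N2 = 400,
                       a_in = 750, b_in = 4250, w = 0.3, J_E = 0.2,
                       J_EE = 2, J_I = 2, delay = 1.5e-3, dt = 1e-4,
                       b_ext = 4000, lif = lif_params()) {
  variant <- match.arg(variant)
  stopifnot(dt <= 1e-4 + 1e-12, N1 >= 1, N2 >= 1)
  periods <- if (variant == "single") 1 else 1 / (1:4)
  L <- length(periods)
  if (N1 %% L != 0) stop("N1 must be a multiple of the number of modules")
  M <- N1 %/% L
  module <- rep(seq_len(L), each = M)
  pref <- unlist(lapply(periods, function(lam) lam * (0:(M - 1)) / M))
  w_ro <- (pi / N2)^2 / (2 * log(2))
  pref_ro <- (0:(N2 - 1)) / N2
  # smallest circular tuning difference between each readout neuron and the
  # (possibly multiple) peaks of each layer-1 neuron
  delta_ff <- matrix(0, N2, N1)
  for (j in seq_len(N1)) {
    lam <- periods[module[j]]
    peaks <- wrap_unit(pref[j] + lam * 0:(ceiling(1 / lam) - 1))
    peaks <- peaks[peaks < 1]
    d <- vapply(peaks, function(p) circular_distance(pref_ro, p),
                numeric(N2))
    delta_ff[, j] <- if (is.matrix(d)) apply(d, 1, min) else d
  }
  W_EE <- feedforward_weight(delta_ff, w_ro, J_EE)
  delta_ro <- outer(pref_ro, pref_ro, circular_distance)
  W_I <- lateral_inhibition_weight(delta_ro, J_I)
  diag(W_I) <- 0
  structure(list(variant = variant, N1 = N1, N2 = N2, L = L,
                 periods = periods, module = module, pref = pref,
                 pref_ro = pref_ro, a_in = a_in, b_in = b_in, w = w,
                 w_ro = w_ro, J_E = J_E, J_EE = J_EE, J_I = J_I,
                 delay = delay, dt = dt, b_ext = b_ext, lif = lif,
                 W_EE = W_EE, W_I = W_I),
            class = "snn_config")
}

#' Stimulus-dependent input rates of the first layer
#'
#' `a * exp((1/w) * (cos(2*pi*(s - pref)/lambda_j) - 1)) + b` for each neuron;
#' the peak rate is `a + b` and the mean over the stimulus domain is equal
#' across modules because every module's peaks tile an integer number of
#' periods.
#'
#' @param cfg an [snn_config()].
#' @param s stimulus value in `[0, 1)`.
#' @return vector of `N1` rates (sp/s).
#' @export
snn_input_rates <- function(cfg, s) {
  lam <- cfg$periods[cfg$module]
  cfg$a_in * exp((cos(2 * pi * (s - cfg$pref) / lam) - 1) / cfg$w) + cfg$b_in
}

#' Feed-forward EPSP as a function of tuning difference
#'
#' @param delta circular difference in preferred tuning, `[0, 0.5]`.
#' @param w_ro readout kernel width.
#' @param J_EE maximal EPSP (mV).
#' @return EPSP amplitude (mV).
#' @export
feedforward_weight <- function(delta, w_ro, J_EE = 2) {
  J_EE * exp((cos(2 * pi * delta) - 1) / w_ro)
}

#' Lateral readout inhibition as a function of tuning difference
#'
#' `-J_I * |sin(pi * delta)|`: zero for identical tuning, maximal for
#' opposite tuning — a much broader kernel than the excitation.
#'
#' @param delta circular difference in preferred tuning.
#' @param J_I maximal IPSP magnitude (mV).
#' @return IPSP amplitude (mV, non-positive).
#' @export
lateral_inhibition_weight <- function(delta, J_I = 2) {
  -abs(sin(pi * delta)) * J_I
}

#' Simulate the two-layer spiking network
#'
#' Event-based LIF dynamics on a fixed `dt` grid: exact exponential membrane
#' decay between grid points, delta-synapse jumps delivered `delay` after the
#' presynaptic spike, threshold crossing followed by reset and a 2 ms
#' refractory period during which inputs are ignored.
#'
#' @param cfg an [snn_config()].
#' @param stimulus a stimulus trace: data.frame with `time` and `s` sampled at
#'   `cfg$dt` (see [step_stimulus()], [ou_stimulus()]), or a plain vector.
#' @param seed optional integer seed.
#' @return a `spike_train_set`: per-layer data.frames of `(time, neuron)`
#'   events, the stimulus trace, the configuration, and the seed.
#' @export
simulate_snn <- function(cfg, stimulus, seed = NULL) {
  stopifnot(inherits(cfg, "snn_config"))
  sv <- if (is.data.frame(stimulus)) stimulus$s else as.numeric(stimulus)
  ang <- 2 * pi * cfg$pref / cfg$periods[cfg$module]
  pack <- list(N1 = cfg$N1, N2 = cfg$N2, L = cfg$L,
               lambda_m = cfg$periods, module_id = as.integer(cfg$module - 1L),
               cosphi = cos(ang), sinphi = sin(ang), a_in = cfg$a_in,
               b_in = cfg$b_in, w = cfg$w, J_E = cfg$J_E, W_EE = cfg$W_EE,
               W_I = cfg$W_I, tau_mem = cfg$lif$tau_mem, V_th = cfg$lif$V_th,
               V_reset = cfg$lif$V_reset, V_rest = cfg$lif$V_rest,
               tau_rp = cfg$lif$tau_rp, delay = cfg$delay, dt = cfg$dt,
               b_ext = cfg$b_ext)
  out <- with_seed(seed, simulate_snn_cpp(pack, sv))
  structure(list(layer1 = data.frame(time = out$t1, neuron = out$id1),
                 layer2 = data.frame(time = out$t2, neuron = out$id2),
                 stimulus = data.frame(time = (seq_along(sv) - 1) * cfg$dt,
                                       s = sv),
                 config = cfg, seed = seed),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike trains (%s network): %d layer-1 and %d layer-2 events over %.3g s\n",
              x$config$variant, nrow(x$layer1), nrow(x$layer2),
              nrow(x$stimulus) * x$config$dt))
  invisible(x)
}

# Circular median: the sample value minimizing the summed circular distance.
circular_median <- function(x) {
  if (length(x) == 1) return(x)
  tot <- vapply(x, function(m) sum(circular_distance(x, m)), numeric(1))
  x[which.min(tot)]
}

#' Instantaneous readout estimates and their sliding-window aggregate
#'
#' Each layer-2 spike decodes the stimulus instantaneously as the spiking
#' neuron's preferred location `(neuron - 1) / N2`. When `window` is given,
#' the estimates are aggregated with a centered sliding circular median
#' evaluated every `every` seconds (10 ms windows for stimulus-tracking
#' traces, 50 ms for RMSE traces); windows without spikes yield `NA`.
#'
#' @param sts a `spike_train_set` (or a data.frame of layer-2 events).
#' @param N2 readout size (taken from the config when `sts` is a
#'   `spike_train_set`).
#' @param window sliding-window length (s), or `NULL` for raw estimates.
#' @param every spacing of window centers (s).
#' @return data.frame of `time` and `s_hat`.
#' @export
decode_readout <- function(sts, N2 = NULL, window = NULL, every = 1e-3) {
  if (inherits(sts, "spike_train_set")) {
    ev <- sts$layer2
    N2 <- sts$config$N2
    t_end <- max(sts$stimulus$time)
  } else {
    ev <- sts
    t_end <- if (nrow(ev)) max(ev$time) else 0
    stopifnot(!is.null(N2))
  }
  est <- data.frame(time = ev$time, s_hat = (ev$neuron - 1) / N2)
  if (is.null(window)) return(est)
  centers <- seq(0, t_end, by = every)
  s_hat <- vapply(centers, function(tc) {
    sel <- est$s_hat[est$time >= tc - window / 2 & est$time <= tc + window / 2]
    if (length(sel) == 0) NA_real_ else circular_median(sel)
  }, numeric(1))
  data.frame(time = centers, s_hat = s_hat)
}

#' Accumulated decoding RMSE of one trial
#'
#' Root mean squared circular error of the instantaneous readout estimates
#' against the stimulus, over events in `[t_start, t_end]`.
#'
#' @param sts a `spike_train_set`.
#' @param t_start,t_end evaluation interval (defaults: whole trial).
#' @return scalar RMSE (stimulus units); `NA` if no events fall in range.
#' @export
trial_rmse <- function(sts, t_start = 0, t_end = Inf) {
  est <- decode_readout(sts)
  keep <- est$time >= t_start & est$time <= t_end
  if (!any(keep)) return(NA_real_)
  dt <- sts$config$dt
  idx <- pmin(nrow(sts$stimulus), floor(est$time[keep] / dt) + 1)
  s_true <- sts$stimulus$s[idx]
  sqrt(mean(circular_distance(est$s_hat[keep], s_true)^2))
}

#' Latency until the readout reflects a stimulus switch
#'
#' First time after `t_switch` at which the trailing-window circular median
#' of the instantaneous estimates is within `tol` of the post-switch
#' stimulus.
#'
#' @param sts a `spike_train_set` from a step-stimulus trial.
#' @param t_switch switch time (s).
#' @param target post-switch stimulus value.
#' @param tol circular tolerance around `target`.
#' @param window trailing-window length (s).
#' @return latency in seconds (`NA` if never reached).
#' @export
switch_latency <- function(sts, t_switch, target = 0.75, tol = 0.1,
                           window = 0.01) {
  est <- decode_readout(sts)
  est <- est[est$time > t_switch, , drop = FALSE]
  for (k in seq_len(nrow(est))) {
    tk <- est$time[k]
    sel <- est$s_hat[est$time > tk - window & est$time <= tk]
    if (length(sel) > 0 &&
        circular_distance(circular_median(sel), target) <= tol) {
      return(tk - t_switch)
    }
  }
  NA_real_
}

#' Two-sample KS comparison of per-trial RMSE distributions
#'
#' @param rmse_a,rmse_b numeric vectors of per-trial RMSEs (>= 2 each).
#' @return list with the KS `statistic` and `p_value`.
#' @export
compare_trial_rmse <- function(rmse_a, rmse_b) {
  stopifnot(length(rmse_a) >= 2, length(rmse_b) >= 2)
  kt <- suppressWarnings(ks.test(rmse_a, rmse_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
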