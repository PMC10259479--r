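---
title: "Minimal decoding times for single-peaked and periodic tuning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal decoding times for single-peaked and periodic tuning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Grid-cell-like periodic tuning curves carry far more Fisher information per
spike than the single-peaked tuning curves that dominate early sensory
cortex, so in the long run they support far more precise decoding. But a
periodic code is only unambiguous when the estimates contributed by its
modules are mutually consistent, and with few spikes the maximum-likelihood
(ML) estimate can jump to a distant, similar-looking activity pattern — a
*catastrophic* error, as opposed to the *local* errors that Fisher
information describes. This package quantifies the resulting speed-accuracy
trade-off: the **minimal decoding time** `T_th` is the shortest decoding
window after which the empirical mean squared error (MSE) of the ML decoder
approaches the Cramér–Rao floor, i.e. after which catastrophic errors have
effectively vanished.

# Model

Stimuli live on the unit circle (or torus), `s in [0,1)^D`, with a uniform
prior — the maximum-entropy, worst-case choice. Neuron `i` fires Poisson
spikes over a window `T` at rate

```
f_i(s) = a_i * prod_j exp( (1/w) * (cos(2*pi*(s_j - s'_ij)/lambda_i) - 1) ) + b
```

* `lambda_i` — spatial period as a fraction of the domain; `lambda = 1` is a
  single bump, `lambda = 1/2` two bumps, and so on. Neurons are organized in
  `L` modules whose periods follow a geometric progression
  `lambda_j = lambda1 * c^(j-1)` with scale factor `0 < c <= 1`
  (`module_periods()`); combinations that make the code ambiguous
  (`lambda1 = 1/2` with `1/c` an integer) are rejected.
* `w` — width scale (default 0.3, in the experimentally plausible range);
  `a_i` — peak evoked amplitude; `b` — stimulus-independent ongoing rate.
* Preferred locations `s'_i` are sampled uniformly; when populations are
  compared, one draw is shared by all of them so that they differ only in
  their periods.
* **Equal mean rates**: `normalize_amplitudes()` solves each neuron's
  amplitude so its evoked mean rate over the domain equals `fbar_stim`
  (default `20*exp(-D/w)*B0(1/w)^D` spikes/s, i.e. amplitude 20 for an
  integer number of peaks). For non-integer `1/lambda` the unit interval
  covers a partial period and the mean depends on the preferred location, so
  one adaptive 1-D quadrature per neuron and dimension (relative tolerance
  `1e-10`, separability across dimensions) is used; the resulting mean rates
  agree to `1e-6` relative.

# Decoder and benchmark

`decode_ml()` implements the exact search protocol: 100 uniform candidate
stimuli are scored by the log-likelihood
`V(r;s) = sum_i r_i log(T f_i(s)) - T f_i(s)`, the best four plus the true
stimulus seed five Nelder–Mead simplex runs (parameter tolerance `1e-6`,
function tolerance `1e-8`, at most 2000 iterations — the reference protocol
does not state these, so they are fixed here and recorded in the result),
and the best local optimum is wrapped mod 1. Including the truth as a start
is deliberately conservative: it can hide, but never inflate, threshold
distortion; ties within the function tolerance are resolved toward the
truth for the same reason. Errors are squared circular distances
(`circular_error()`), at most 0.25 per dimension.

The benchmark is the inverse Fisher information. `analytic_fisher()` is the
closed form valid for equal amplitudes and `b = 0`;
`empirical_fisher()` Monte-Carlo-averages the exact independent-Poisson
matrix `J_kl(s) = T * sum_i (df/ds_k)(df/ds_l)/f_i` over 10,000 uniform
stimuli with closed-form derivatives, works for any `b`, and is what the
threshold criterion uses. The two agree at `b = 0` (a property test), and
the matrix is diagonal for `D = 2`.

# Minimal decoding time

`minimal_decoding_time()` scans `T = 1, 2, 3, ...` ms and stops at the first
`T` where the dimension-averaged MSE is at most `alpha` times the
dimension-averaged `diag(J(T)^-1)` (`alpha = 2` by default; `alpha = 1.2`
for a stricter read). The reference protocol evaluates every millisecond
with 15,000 trials (or the "stability" rule: sample until the two leading
digits of the MSE are unchanged over 1000 consecutive trials — both
protocols agree within sampling error, which a test checks). That costs
hours per population grid, so the package adds a `"bracket"` scan: double
`T` until the criterion first holds, then bisect. Every decoding time uses
its own seed derived from the master seed, so a decision at a given `T` is
identical whatever the path that reached it, and the returned `T_th` still
satisfies "criterion holds at `T_th`, fails at `T_th - 1`". Early stopping
is allowed only for *clear failures* (MSE above threshold by more than 4
standard errors): a pass always consumes the full trial budget, because
passing hinges on the rare-event tail. The last bisection steps — the
decisions that pin `T_th` down to the millisecond, and the noisiest ones —
double the trial budget.

An alternative criterion (`mdt_criterion("ks_test")`) asks instead when the
error distribution becomes statistically indistinguishable from the
Gaussian `N(0, J^-1)` implied by the bound: at the j-th decoding time a
one-sided Kolmogorov–Smirnov test of the pooled standardized |errors|
against the half-normal law is run at the sequentially corrected level
`0.05/j`, rejecting when errors are stochastically larger. The direction of
the one-sided test and the pooling of dimensions before testing are choices
of this package (the reference description does not pin them down).

The two criteria answer different questions. With `alpha = 2` the criterion
asks for the MSE to be *within a factor two* of the floor; for a
single-peaked population with a 2 sp/s baseline this happens within a few
milliseconds, because a cluster of a few dozen evoked spikes is essentially
impossible to outweigh by uniformly scattered baseline spikes (a
Chernoff-type argument; the package's simulations agree, as does the
two-module bound below, which predicts ~1 ms for single-peaked pairs). The
KS criterion instead asks when the *excess* over the floor stops being
statistically detectable, which at reference trial counts takes tens of
milliseconds. Published "time until the bound is reached" statements read
from RMSE traces correspond to the second notion; the acceptance script
reports both times.

# Two-module theory

For `L = 2`, each module's likelihood is a comb of modes and the joint
estimate is correct only while the displacement `delta` between the two
per-module estimates stays below `delta* = min_{(n1,n2) != 0}
|n1*lambda1 - n2*lambda2|/2` (`delta_star()`, index ranges
`K_i = ceiling(1/(2*lambda_i))`, restricted to `lambda_i*|n_i| < 1` when
`lambda1 = 1` since a full wrap is the same mode; both-single-peaked pairs
have no competing mode and return the domain maximum 1/2 by convention).
Treating the module estimates as independent Gaussians with variances
`1/(T J_k,norm)` and bounding the catastrophe probability by
`p_error = 1e-4` gives the lower bound

```
T_th > 2 * (erfinv(1 - p_error)/delta*)^2 * (1/J1_norm + 1/J2_norm)
```

(`t_th_two_module()`). `run_two_module_study()` compares this bound with
simulated thresholds across a `c`-grid and reports two coefficients of
determination: `r_squared` takes residuals about the bound itself, while
`r_squared_fit` is the OLS calibration of simulation on prediction. The
bound ignores the decoder's local-convergence floor (the few milliseconds
any population needs before the MLE is efficient), which dominates the
small-`T_th` cells of a scaled-down grid; the calibration R² is therefore
the meaningful association measure at reduced scale and is what the
acceptance suite checks.

# Scaling law for L modules

For more than two modules a saddle-point-style expansion of the
log-likelihood yields the scaling

```
T_th ∝ (1/(a N)) * exp(D/w) * B0(1/w)^-(D-1) * mean(lambda^-3)^2 / mean(lambda^-2)^3
```

valid for unambiguous codes without ongoing activity. In scale-factor form
the period term becomes `(sum_j c^-3j)^2 / (sum_j c^-2j)^3`, independent of
`lambda1` (`scaling_predictor()`; a test asserts the cancellation).
`fit_theory_constants()` fits the two free constants (regressor `K1`, which
absorbs the width-dependent prefactor, and intercept `K2`) by OLS.
`run_five_module_study()` applies this over a `c`-grid; cells whose scan
exceeded the time cap are flagged and excluded from the fit. Comparing
fitted `K1` between families with and without ongoing activity quantifies
how background spikes slow decoding; the ratio exceeds one for both `D = 1`
and `D = 2` in the package's replications.

# Spiking network

`snn_config()` / `simulate_snn()` implement a two-layer feed-forward LIF
network (membrane time constant 20 ms, threshold 20 mV, reset 10 mV,
refractory 2 ms, delta synapses, delay 1.5 ms, `dt = 0.1` ms; exact
exponential decay between grid points, so integration is exact up to grid
resolution). Layer 1 (500 neurons, unconnected) receives Poisson input
tuned to the stimulus with peak 750 + 4250 sp/s baseline; it is either
entirely single-peaked or split into four modules. A parameter table listing
"spatial periods [1] or [1,2,3,4]" cannot literally be periods on a unit
domain, so the periodic variant uses spatial *frequencies* 1–4, i.e.
periods 1, 1/2, 1/3, 1/4 — flagged prominently here. Layer 2 (400 readout
neurons, preferred locations `k/400`) receives: EPSPs from layer 1 scaled
by `2 * exp((cos(2*pi*delta)-1)/w_ro)` mV with `delta` the smallest circular
tuning difference over the presynaptic neuron's peaks and
`w_ro = (pi/400)^2/(2 log 2)` so the kernels tile the domain at half
maximum; broad lateral inhibition `-2*|sin(pi*delta)|` mV (winner-take-all);
and non-specific Poisson background. The background rate into layer 2 is
not printed in the reference description; it is fixed at 4000 sp/s, the
operating point at which background alone leaves readouts quiescent
(< 1 sp/s) while matched feed-forward drive fires them. Decoding is
instantaneous — each readout spike reports its neuron's preferred location —
with sliding-window circular medians (10 ms for tracking traces, 50 ms for
RMSE traces) for aggregated comparisons.

Two caveats, both consequences of the printed parameters rather than of
scaled-down simulation: (1) periodic layer-1 neurons project strongly to
one readout *per peak* (10 strong projections per 4-module group of
neurons vs 1 for single-peaked), so the periodic readout receives more
total excitation and fires roughly twice as much — the variants' population
rates match only within a factor ~3 here, not the few percent one might
hope for. (2) On the smoothly varying Ornstein–Uhlenbeck stimulus the
single-peaked readout has the larger *local* scatter (its excitation
profile is as broad as its tuning curve, and the |sin| inhibition is weak at
short range) while periodic alias-flips are rare over seconds-long trials,
so the whole-trial RMSE ordering favours the periodic network in this
implementation. The step-stimulus results — faster state switching and
lower post-switch RMSE for the single-peaked network, because periodic
neurons respond on both sides of the 0.25 → 0.75 jump (modules with even
peak counts respond identically at both values) — reproduce robustly and
are asserted over 30 trials per network.

# Synthetic data

All inputs are synthetic and generated by the package itself: uniform
stimuli, Poisson counts, the step stimulus (0.25 → 0.75), and the
Ornstein–Uhlenbeck stimulus `ds/dt = -s/tau_s + sqrt(2 sigma_s^2/tau_s) xi`
(`tau_s = 0.5` s, `sigma_s = 0.1`) integrated by Euler–Maruyama on the
simulation clock. The OU drift acts on the unwrapped coordinate and the
trace is wrapped onto `[0,1)` for readout; wrapping the state inside the
drift would make the printed mean reversion discontinuous at the domain
boundary and destroy the stationary spread that the stated `sigma_s`
implies. The generator reproduces the stated distributions exactly
(Poisson mean and Fano checks, stationary circular sd, lag-`tau`
autocorrelation `e^-1` are all tested); what it deliberately does not
emulate is anything beyond the model class — correlated noise, non-Poisson
variability, plasticity, non-uniform priors — so green tests certify the
model's internal consistency, not robustness of the conclusions to those
real-data features.

# Reproducibility and problem sizes

Every stochastic component draws from a named substream derived from one
master seed (locations, stimuli, spike counts, decoding candidates, each
decoding time's trial block), so any grid cell can be re-run bit-identically
in isolation. The default test/acceptance profile uses 6–8-point `c`-grids,
1000–1500 decoding trials per decoding time (doubled at the final bisection
steps), a 150 ms scan cap, 10,000 Monte-Carlo stimuli for Fisher matrices,
and 30 trials per spiking-network condition; the `"full"` profile
(15,000 trials, linear scan, 500 ms cap) reproduces the reference protocol
when hours of compute are acceptable. Trial count matters quantitatively:
with `n` trials the criterion can only react to catastrophe rates of order
`1/n`, so scaled-down thresholds for strongly periodic populations are
systematically a little below full-protocol ones.

# Known limitations

* The two theory modules are asymptotic: the two-module bound ignores the
  local-convergence floor, and the scaling law assumes near-equal
  amplitudes, no baseline, and an unambiguous code (it degrades as
  `c -> 1` for `lambda1 = 1/2`).
* Boundary-adjacent stimuli (near `s = 0`) receive no special treatment in
  the theory; the mid-domain index ranges are used throughout.
* The spiking network is a demonstration, not a biophysical model:
  inhibition is effective (no interneurons), synapses are delta pulses, and
  the readout-layer background rate is a package choice (see above).
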