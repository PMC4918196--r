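---
title: "Estimating FES-induced joint torque from evoked EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FES-induced joint torque from evoked EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(festorque)
```

## The problem

Under functional electrical stimulation (FES), every current pulse recruits
motor units synchronously, so the evoked EMG (eEMG) of each stimulation loop
is dominated by one compound M-wave whose envelope tracks muscle activation.
In spinal-cord-injured subjects there is no volitional EMG to contaminate it,
which makes the per-loop mean absolute value (MAV) of the cleaned eEMG a
usable proxy for activation — and hence a sensor-light input for predicting
the evoked joint torque. `festorque` replays this loop offline: preprocess,
identify an eEMG-to-torque model during a first phase, then predict torque
from eEMG alone with frozen parameters.

This vignette documents the models and their assumptions, the tunable
parameters with units and defaults, the synthetic-data generator, and every
numerical or design choice where the published description left the design
open. It states no empirical result that the test suite does not itself
compute.

## Preprocessing

One *loop* is an inter-pulse interval (`1/f_stim`, 25–33 ms at the clinical
30–40 Hz). Per loop:

1. **Blanking** (`blank_artifact`): the first `ceil(window_ms * f_samp/1000)`
   samples are zeroed (default 10 ms, i.e. 41 samples at 4096 Hz). The window
   is anchored at the pulse onset because the artifact is synchronous with
   the stimulus. Ceiling is used so the window never under-covers the
   artifact; loop lengths use round-half-up.
2. **Residual-spike removal** (`remove_residual_artifacts`): adjacent sample
   pairs whose absolute difference exceeds a threshold are zeroed together
   with `template_half_width` (default 2) neighbours of the first sample of
   the pair; the pass iterates to a fixed point so the operation is
   idempotent (a single pass can create fresh above-threshold edges at zone
   boundaries).

   *Threshold default.* A tempting robust default — a small multiple of the
   median absolute adjacent difference — fails in practice: the median is set
   by the noise floor or the flat parts of the M-wave, so 5x the median sits
   *below* the steepest genuine M-wave slopes and the detector would zero
   real signal in essentially every loop. The package default is therefore
   `3 x quantile(|diff|, 0.99)` per loop: residual artifacts are rare,
   large events, so a high quantile tracks the genuine slope ceiling and the
   multiplier only fires on spikes well above it (a stimulation-scale spike
   of several mV per sample clears it easily). An explicit `diff_threshold`
   in mV overrides the default.
3. **Features**: `u(k)` = MAV of the cleaned eEMG (mV), `tau(k)` = mean of
   the torque channel scaled by the dynamometer calibration 8.64 Nm/V,
   optionally baseline-corrected by the mean of a pre-stimulation rest
   interval. The MAV series is smoothed with a *causal* moving average over
   `round(0.8 * f_stim)` loops (prefix-clipped at the start): causality keeps
   the real-time contract — loop `k` uses only loops `<= k`.

Loop indices are 0-based and sample ranges half-open, matching the discrete
time index `k` of the estimators.

## The estimators

Both estimators share the orders `l` (output lags), `m` (input lags), `n`
(polynomial degree), default `c(2, 2, 2)` — the published system states that
both models used identical orders without printing them; 2/2/2 is the
smallest configuration that can represent second-order contraction dynamics
with a curved recruitment map, and the orders are configuration-exposed.

### Forgetting-factor Kalman filter on a polynomial Hammerstein model

The model is `y(k) = sum_i a_i y(k-i) + sum_{i,j} d_ij u^j(k-i)`, with the
polynomial basis starting at `u^1` (no constant term). Two readings of the
printed estimator are implemented because the source mixes an observer
notation (`y_hat = x_hat_1`) with parameter-update equations:

* `mode = "ekf"` (default): joint state+parameter extended Kalman filter.
  The augmented state is `[output; a; vec(d)]`; the output propagates through
  the model recursion, parameters as a random walk; `A` is the Jacobian at
  the current estimate, `H = [1, 0, ...]`.
* `mode = "rls"`: linear-in-parameters reduction with `H` equal to the
  regressor; at `lambda = 1` and a diffuse prior this is exactly batch least
  squares including the prior (the equivalence is asserted to 1e-6 in the
  acceptance suite).

The products `b_i c_j` of a Hammerstein factorization are not separately
identifiable (any scalar can migrate between the static polynomial and the
linear block), so the estimator works with the coupled `d_ij = b_i c_j`
directly; the input-output map is unchanged.

Updates per loop: a priori `P_hat = A P A' / lambda`, a posteriori
`S = H P_hat H' + lambda`, `K = P_hat H' / S`, `x <- x_hat + K (y - y_hat)`.
The forgetting factor (default 0.95, admissible [0.9, 1]) doubles as the
measurement-noise weight; no separate `R` is used, and the process noise of
the parameter random walk is absorbed into the `1/lambda` inflation (its
covariance is nowhere specified in the source).

**Numerical safeguards.** Two standard safeguards are applied on top of the
printed equations, both leaving the algebra unchanged for exact arithmetic:
the Joseph form of the covariance update (PSD under round-off), and
covariance limitation — eigenvalues of `P` clipped to `[0, 1e6]`. The latter
matters because with `lambda < 1` the covariance of directions unexcited
during the 2 s rest segments grows like `lambda^-k` (wind-up) and a naive
implementation aborts on an indefinite innovation covariance mid-session.
Initialization: parameters at zero, output state at the first measured
torque, `P0 = 1e3 I`; identification fails fast when the state norm exceeds
1e6.

The Kalman path **requires normalization**: inputs and outputs are scaled to
[0, 1] by their identification-phase maxima (a fixed per-session reference,
not a running maximum), and predictions are de-normalized. Running it on
absolute scales is supported (`normalize_kalman = FALSE`) and is expected to
degrade — the acceptance suite reproduces that contrast directionally.

### NARX with bilinear cross terms

`tau(k) = sum_r v_r tau(k-r) + sum_{i,j} w_ij u^j(k-i) + a u(k-m) tau(k-1) +
b u(k-1) tau(k-l)`. Identification is one-shot at the end of the
identification phase: stack one row per observed target (`t = 1..k_id`,
indices before the series start contributing zero — the printed block
matrices are typeset with inconsistent zero padding, so the row structure is
taken from the model equation, which is normative), and solve by SVD
pseudoinverse with singular values below `max(dim) * eps * sigma_max`
truncated — the minimum-norm solution, robust to the collinearity of
polynomial regressors. The model runs on absolute scales (no normalization)
and per-loop prediction cost is constant; the optional per-loop recursive
refit mentioned as possible in the source is deliberately not implemented.

### Free-run prediction and seeding

From the boundary loop `k_id` on, both models iterate with their own past
predictions substituted for measurements everywhere (lagged outputs and
cross terms); parameters are frozen. The first `l` values are seeded with
the last measured torques of the identification phase (the source does not
state a seeding rule; using the boundary measurements is the choice that
makes the first predicted step exact for a perfect model). The prediction
API receives measured torque only up to the boundary, so causality is
structural; the acceptance suite additionally corrupts post-boundary torque
and asserts bit-identical predictions.

## Metrics

`rmse = sqrt(mean((tau - tau_hat)^2))` in Nm;
`nrmse = 100 rmse / (max(tau) - min(tau))` — the normalization convention
(range vs mean vs max) is not defined in the source and cannot be
adjudicated from its tables since the underlying data are unavailable; the
peak-to-peak range is used and documented prominently;
`vaf = 100 (1 - var(tau - tau_hat)/var(tau))` with population (1/N)
variances in both terms so the convention cancels. VAF is never clipped and
can be negative.

## The synthetic-data generator

`simulate_session` emulates exactly the phenomena the preprocessing and
estimators are built for:

| parameter | default | meaning |
|---|---|---|
| `threshold_pw`, `saturation_pw` | 50, 350 us | PW recruitment window; smoothstep rise between them |
| `mwave_amp_mV` | 1.5 mV | peak M-wave per unit activation |
| `mwave_latency_ms` | 10 ms | pulse-to-M-wave latency (the M-wave starts where blanking ends) |
| `mwave_duration_ms` | 15 ms | one-cycle damped-sine biphasic template; fits a 30–40 Hz loop, truncated by an 80 Hz loop |
| `artifact_amp_mV` | 5 mV | biphasic rectangular artifact at pulse onset |
| `torque_gain_Nm` | 15 Nm | steady-state torque at full activation (an SCI-scale ankle torque) |
| `fn_hz`, `damping` | 0.5 Hz, 0.9 | second-order contraction dynamics, exact zero-order-hold discretization at loop rate |
| `noise_sd_emg`, `noise_sd_torque` | 0.02 mV, 0.05 Nm | per-sample Gaussian measurement noise |
| `fatigue_rate` | 0.05 / min | joint exponential decay of M-wave amplitude and torque gain (early-middle-stage fatigue, no recovery) |

Rationale for the load-bearing choices:

* **Contraction dynamics at 0.5 Hz.** The torque rise time to a plateau is
  then about a second, matching FES-induced isometric responses to 2 s
  trapezoidal trains. This is also an honest statement of the estimators'
  domain of validity: with much faster dynamics (natural frequency >= 1 Hz)
  at a 30–40 Hz loop rate the measured torque becomes so smooth relative to
  the loop step that one-shot equation-error least squares identifies
  near-unit-root autoregressive parts whose free-run iteration is unstable —
  a known property of equation-error identification, not of this
  implementation. The limitation is inherited by any user data with very
  fast dynamics relative to `f_stim`.
* **Fatigue** decays the M-wave and the torque gain by the *same* factor,
  reproducing the MAV–torque correlation the estimators assume; metabolic
  fatigue-recovery cycling is deliberately out of scope.
* **Pulses are emitted every loop** (the stimulator clock), with zero pulse
  width during rest meaning no artifact and no M-wave; segmentation therefore
  tiles the whole session.
* Overlapping M-wave templates superpose, so at 80 Hz each loop observes a
  truncated wave (the truncation phenomenon at high stimulation frequency).

What the generator does **not** emulate — and what a green test therefore
does not establish: volitional EMG contamination, pulse-to-pulse M-wave
jitter, electrode-motion artifacts at arbitrary times, force–length/velocity
effects (isometric only), metabolic fatigue with recovery, and day-to-day
electrode-contact changes. End-to-end accuracies on simulated sessions are
upper bounds relative to clinical recordings.

## Session pipeline

`run_session` concatenates an identification protocol (plateaus linearly
spaced over 40–100 % of max PW; interpreting "increased gradually from 40 to
100 %" as linear spacing, the exact schedule being unstated) and a prediction
protocol (plateaus i.i.d. uniform in 50–100 %), simulates or loads the
recording, extracts features, splits at `id_duration_s` (default 30 s — the
only printed identification duration, although the described sequences of
18 +/- 2 cycles would span 72 s; both are configurable), identifies, free-run
predicts, evaluates, and writes features, parameter dumps, predictions and a
report as headered CSVs (full double precision, lossless round trip).
Real-time behaviour is emulated logically: loops are processed in causal
order and per-loop compute times are reported, with a logged warning when a
loop exceeds `1/f_stim`, but wall-clock deadlines are not enforced — they are
hardware properties, not properties of the algorithms under test.

## Known limitations

* The recursive estimator's accuracy on absolute (unnormalized) scales is
  poor by design heritage; use the NARX route or normalization.
* The NRMSE convention (range-normalized) is a package choice; comparisons
  against other conventions require rescaling.
* Free-run stability of the identified models is not guaranteed for
  arbitrary data; the NARX free run raises a located error when it diverges.
* The identification phase must exceed the parameter count
  (`l + m n + 2` loops) — the configuration fails fast otherwise.
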