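---
title: "Estimating limb motion from complementary-limb sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating limb motion from complementary-limb sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitattn)
```

## The problem

Lower-limb assistance devices — powered prostheses and orthoses — need a
continuous reference trajectory for the limb they replace or support. A
person with an amputation cannot supply the missing limb's motion history,
but their *other* segments can: human locomotion is strongly limb-synergetic,
so the resultant acceleration of the left ankle and left hip can be inferred
from inertial measurement units (IMUs) worn on the right ankle, right hip
and chest. `gaitattn` implements this complementary-limb motion estimator
as a regression over sliding windows of multi-channel IMU time series,
using stacked bidirectional LSTM networks with an optional two-stage
temporal attention mechanism, and ships a synthetic gait-signal generator
so the entire pipeline is testable without any external recordings.

The estimator is *mode-free*: a single trained network produces trajectories
across level walking, stairs, ramps and stopping, and through the
transitions between them, instead of switching between per-activity
controllers.

## Data model

A recording is a sample matrix at a fixed 100 Hz sampling rate: one row per
timestep, thirty input channels (three sensor locations x ten quantities —
triaxial accelerometer, gyroscope, magnetometer, plus the accelerometer
resultant, i.e. the Euclidean norm of the three acceleration axes) and two
target channels (left-ankle and left-hip resultant acceleration), with
subject and activity labels per row.

Preprocessing follows four steps, in this order:

1. **Target smoothing.** A 5-point centred moving average removes outliers
   and high-frequency noise from the *targets only*; the inputs stay raw by
   default (end-to-end learning). The window shrinks symmetrically at the
   series edges so the output length equals the input length. Optional
   input-filter variants (5-point moving average, or a zero-phase 2nd-order
   Butterworth low-pass at 6 Hz) are exposed for the filtered-input
   comparison but are off by default.
2. **Normalization.** Per-channel mean and standard deviation are computed
   on the *training subjects only* and applied unchanged to validation and
   test data. Targets are never normalized; all reported errors are in
   physical units (m/s^2).
3. **Sliding-window resampling.** A window of T timesteps rolls one step at
   a time through each subject's rows; each data point pairs the window
   `(i .. i+T-1)` of the 30 input channels with the two target values at
   row `i + T`. A segment of N rows yields exactly `N - T` points. Windows
   may cross activity transitions (the models must ride through them) but
   never subject boundaries.
4. **Subject-disjoint splitting.** Held-out test subjects contribute *all*
   of their data points and nothing else; the remaining points are shuffled
   with a recorded seed and split 85/15 into training and validation
   (validation count = `floor(0.15 n)`). Subject-disjointness is asserted on
   every split. Whether shuffling happens globally or within training only
   is a config choice; the default shuffles the pooled non-test points
   before the 85/15 cut.

## Architectures

Three architectures are compared, all mapping a `(batch, T, 30)` window
tensor to the two targets at the next timestep:

* **Unbranched baseline** (T = 15): stacked (Bi-)LSTM layers, the final
  hidden state feeding one dense head whose last layer has two units — only
  that last layer specializes per output.
* **Branched baseline** (T = 15): the same recurrent trunk, but one dense
  head *and one loss* per output, so the lower layers specialize for ankle
  and hip separately while the trunk is shared.
* **Branched attention model** (T = 25): exactly two Bi-LSTM layers with
  two attention layers interleaved. After the first Bi-LSTM, a shared
  scoring perceptron (tanh hidden layer, scalar output) scores every
  timestep's hidden vector; a softmax turns the scores into weights
  `alpha_t in [0, 1]`, `sum(alpha) = 1`, and each timestep is *rescaled* by its
  weight, preserving the sequence for the second Bi-LSTM. After the second
  Bi-LSTM a second, independently learned scorer produces new weights and
  the weighted timesteps are *summed* into a single context vector feeding
  the branched dense heads.

The two scorers are separate learnable functions (the layers are similar
but not shared); each scorer emits one scalar per timestep. The rescaled
sequence is not renormalized before the second recurrent layer. In the
constant-scorer limit the weights collapse to `1/T` and the context vector
equals the unweighted mean of the hidden sequence — a closed-form check
used in the tests.

The recurrent cell is a standard LSTM (input/forget/candidate/output
gates, memory cell) implemented as compiled batched forward and
backward-through-time kernels in `src/lstm.cpp`; the backward pass is
verified against finite differences in the test suite. Bidirectional
layers run the window forward and backward and concatenate the per-timestep
hidden states.

### Widths and sizes

The layer widths are package choices at desk scale (no canonical values
exist; such widths are usually found by grid search): the attention model
uses recurrent widths [64, 32], scorer widths [16, 1] and dense head widths
[32, 16, 1]; the branched and smaller unbranched baselines use [96, 64];
the larger unbranched baseline [140, 92] (roughly double the smaller one's
parameter count). The widths were sized so that a full training run takes
minutes on a single CPU, while preserving the headline size relation:
the attention model needs at most half the branched baseline's parameters
(98,244 vs 238,466), because attention concentrates capacity on informative
timesteps instead of buying accuracy with width.

### Initialization

Weights are Glorot-uniform under a recorded seed; the forget-gate bias
starts at 1. One deliberate deviation from framework defaults: the output
layer's bias can be initialized at the training-target mean
(`output_bias = colMeans(train$y)`). The targets sit on a ~9.8 m/s^2
gravity offset, and under a relative-error loss a zero-initialized output
spends thousands of optimizer steps climbing that offset before it can
learn any dynamics; starting at the target mean removes that dead time
without touching the loss or the data. The default remains 0.

## Training

The loss is the Mean Absolute Percentage Error,
`MAPE = mean(|y - yhat| / max(|y|, eps))`, optimized with Adam at an
initial learning rate of 0.001. The `eps` floor (default 1e-3 in target
units) is required for well-posedness: resultant accelerations approach
zero when the subject is stopped, and a raw MAPE denominator would blow
up. Branched models carry one MAPE per output head and the gradient uses
their unweighted sum; the unbranched model averages one loss across both
outputs.

The learning rate halves (`lr_decay_factor = 0.5`) whenever the validation
loss has not improved for `lr_patience` epochs, and training stops after
`early_stop_patience` epochs without improvement; the parameters with the
best recorded validation loss are restored. Batch size (default 256) and
the patience values are conventional plateau-schedule choices; nothing in
the problem fixes them. Runs are bitwise reproducible given the config
seed under single-threaded BLAS; multi-threaded builds reproduce up to
floating-point reduction order.

## Evaluation

Three metrics per output channel, all on the physical target scale:

* `NRMSE = RMSE / (max(y) - min(y))` — the range is that of the evaluated
  dataset's ground truth and is recorded in the report for transparency;
* `MAE = mean(|y - yhat|)` in m/s^2;
* `MAPE` as above, reported as a percentage.

Spectral robustness is assessed with a discrete Fourier power spectrum
(mean removed, no taper, full trace as one segment; bin powers sum to the
series variance — Parseval). The fraction of power above a 6 Hz boundary
quantifies high-frequency noise in a model's predictions: gait signals
carry their discriminative content below ~6 Hz, so above-boundary power in
a prediction is spurious variation. `compare_spectra()` tabulates
below/above-band power for ground truth and two predictions side by side.

## The synthetic gait generator

The generator emulates the *statistical* structure the pipeline cares
about, not sensor physics:

* **Quasi-periodicity.** Each activity is an `activity_profile`: a
  cadence-scale fundamental frequency (0.5-2 Hz) and per-channel amplitudes
  for harmonics 1-3, so all deterministic power sits below 6 Hz. Six
  built-in modes (level walk, stair ascent/descent, ramp ascent/descent,
  stopped) differ in cadence and intensity; "stopped" has near-zero
  amplitude.
* **Channel structure.** Each input channel is a per-sensor DC baseline
  (gravity-scale for accelerometer resultants, earth-field-scale for
  magnetometers) plus its harmonics with subject- and channel-specific
  phase offsets, plus Gaussian sensor noise (default sd 0.05).
* **Inter-limb coupling.** Each target equals `coupling_gain` times a fixed
  convex combination of the three input resultant-acceleration channels
  *lagged by half the instantaneous fundamental period* — contralateral
  phase opposition — plus Gaussian noise and sparse outlier spikes
  (default rate 0.1% of rows, magnitude 5 target SDs) that exercise the
  moving-average clean-up.
* **Transitions.** Activity switches cross-fade linearly over 0.5 s
  (shorter than one stride, so transition windows stay challenging), with
  the oscillation phase evolving continuously.
* **Subjects.** Per-subject parameters (amplitude scale in [0.85, 1.15],
  per-channel phases, coupling gain ~ N(1, 0.005)) derive deterministically
  from the cohort seed, and stage durations are jittered by +/-10% to
  emulate self-selected pace. The coupling-gain spread is deliberately
  small: the gain multiplies a gravity-dominated combination, so an unseen
  subject's gain cannot be identified from the inputs, and its spread sets
  a hard floor under held-out accuracy (sd 0.005 keeps that floor near 3%
  of the target range, leaving the learnable dynamics dominant).
* **Determinism.** Identical (subject, schedule, rate, seed) reproduce
  bit-identical recordings; all randomness flows from a single seed.

Because the coupling is known, the generator doubles as its own oracle:
regressing each target on the stated lagged combination (`coupling_oracle()`)
recovers the gain with zero residual at zero noise and quantifies
learnability (R^2 >= 0.8 under default noise) otherwise.

What the generator does *not* emulate — magnetometer drift, gravity
alignment, joint-angle conventions, soft-tissue artefacts, realistic
activity imbalance — bounds what a passing test suite shows: the pipeline
and architectures are exercised end to end on signals with the right
spectral and synergetic structure, but accuracy numbers on synthetic
cohorts say nothing quantitative about any real recording.

## Study conditions used by the bundled experiments

The packaged experiments (test suite and `scripts/acceptance.R`) use a
10-subject cohort (default schedule: level walk 5 s, stair ascent 4 s, ramp
descent 4 s per subject, jittered), hold out two subjects, and train the
branched attention model (T = 25) and the branched baseline (T = 15) for up
to 12 epochs (batch 256, plateau patience 3, early-stop patience 6). These
sizes are the package's desk-scale choice: one model trains in roughly two
to three minutes on a single CPU, and the cohort is large enough for
subject-level generalization to be non-trivial (held-out subjects have
unseen phases, amplitudes and pacing).

## Numerical choices and degenerate inputs

* Constant input channels are rejected at normalization with an error
  naming the channel.
* Segments shorter than `T + 1` rows are skipped with a warning, not an
  error.
* The MAPE epsilon floor, the softmax's max-subtraction, and the
  validation-improvement comparison (strict `<`) are the only tie-break
  rules; there is no tolerance on "improvement".
* The sampling theorem is enforced at generation: `fs` must exceed twice
  the highest harmonic frequency.
* NRMSE refuses constant ground truth (degenerate range).
* Evaluation refuses datasets whose normalization-statistics hash differs
  from the one the model was trained with (provenance guard).

## Known limitations

* The recurrent core is the package's own compiled implementation; it is
  validated by finite-difference oracles and closed-form limits, not
  against an external deep-learning framework.
* Training is single-threaded CPU code; wall-clock scales linearly with
  cohort size, window length and the square of layer widths.
* The synthetic task is close to linear in harmonic coordinates; it
  rewards the architectures' inductive biases but cannot rank them the way
  months of real recordings would.
* MAPE weights errors near low-acceleration phases more heavily; with the
  epsilon floor this is intended (it matches the training objective), but
  it makes MAPE values sensitive to the floor when targets approach zero.
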