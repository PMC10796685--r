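---
title: "Simulating and decoding bimanual cursor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding bimanual cursor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimanbci)
```

## The scientific problem

Intracortical brain-computer interfaces decode intended movement from
multiunit threshold-crossing rates recorded in motor cortex. Extending
decoding from one effector to two (simultaneous two-cursor, "bimanual"
control) runs into three properties of the motor-cortical code that break the
single-effector linear picture:

* **Correlated directional tuning across hands.** The coefficient vectors
  relating firing rates to right-hand and left-hand velocity are not
  independent; as they become more similar, a linear decoder cannot tell
  which hand a pattern of modulation belongs to, and intended movement of one
  cursor leaks into the other.
* **Context-dependent suppression and decorrelation.** When both hands move
  at once, the non-dominant hand's tuning magnitude shrinks (suppression) and
  its tuning axes rotate (decorrelation) relative to unimanual movement, so a
  single linear model cannot serve both contexts.
* **A laterality dimension.** A large population dimension codes *which side
  of the body* is moving, independently of movement direction. Linear
  velocity decoders cannot exploit it (it is orthogonal to any
  direction-covarying readout in expectation), but nonlinear decoders can use
  it to separate the hands.

This package implements the full computational pipeline for studying these
phenomena on synthetic data: an encoding-model simulator, cross-validated
tuning statistics, three decoder families (ridge, feed-forward network,
context-gated GRU), a time-dilation training-data augmentation method, and a
simulated closed-loop two-cursor task.

## The encoding model

Each channel's rate is linear in the intended velocity of each hand within a
movement context, plus a signed laterality code:

$$ f \;=\; b_0 + b_{rx} d_{rx} + b_{ry} d_{ry} + b_{lx} d_{lx} + b_{ly} d_{ly}
   + b_{lat}\, c_{lat}, \qquad
   c_{lat} = \begin{cases} +1 & \text{unimanual right} \\
                           -1 & \text{unimanual left} \end{cases} $$

`sample_population()` draws the coefficient vectors from standard normals,
enforces a chosen correlation $\rho$ between the right- and left-hand columns
(the x-axis of the simulation sweep), rescales columns to requested norms,
and builds bimanual-context coefficients by re-mixing toward a target
unimanual-to-bimanual correlation (0.85 right, 0.45 left by default) and
scaling by per-hand suppression factors (1.0 right, 0.66 left). Noise is
i.i.d. Gaussian per bin and channel with a single shared standard deviation
(diagonal covariance); rates are clipped at zero after noise.

Choices worth stating explicitly:

* **Correlation enforcement** defaults to an exact-projection construction
  (the mixing residual is orthogonalized against the reference column), so
  the realized sample correlation equals $\rho$ to machine precision. A
  plain mix-and-rescale mode (`corr_mode = "mix"`) leaves the
  $\mathcal{O}((1-\rho^2)/\sqrt{n})$ sampling scatter in.
* **The laterality reference norm** for `lat_scale = 1` is the mean of the
  four directional column norms: laterality variance is then comparable to
  direction variance, which is the regime of interest (in recordings it is
  if anything larger).
* **$c_{lat}$ outside unimanual contexts** is not defined by the unimanual
  tuning model; we use +1 for bimanual (bimanual population activity most
  closely resembles unimanual-right activity) and 0 at rest. Both are
  arguments of `laterality_code()`.
* **Left-hand magnitudes** default to 0.6 of right-hand magnitudes
  (ipsilateral tuning is weaker than contralateral).
* **Baselines** are drawn from a gamma distribution with mean 40 Hz,
  a typical multiunit threshold-crossing scale.

## Sessions and noise calibration

Two generators emulate the tasks:

* `generate_unimanual_dataset()`: n trials per hand of a fixed 400-ms
  movement window, intended velocity a uniformly random unit vector within
  one of 8 half-open 45° wedges, balanced across wedges — the dataset used
  for single-bin decoding analyses.
* `generate_delayed_session()`: full delayed-movement trials — delay (1–2 s,
  uniform), move (1–2 s), idle (1 s) — with unimanual and bimanual types
  interleaved and balanced. Intention during movement is the unit
  point-at-target vector; stored decoder targets follow the saturated speed
  profile of `kinematic_profiles()` (zero during a 200-ms reaction time,
  maximum speed until 15% of the distance remains, then a linear taper),
  which approximates a user's intent to move maximally when far from the
  target better than the minimum-jerk profile the open-loop cursor actually
  follows.

Noise is calibrated, not chosen per experiment: `calibrate_sigma()` bisects
on $\sigma$ until the *functional SNR* of a cross-validated linear decode of
the noisy dataset matches a target. The fSNR fits decoded output
$\hat y_t = D y_t + \epsilon_t$ against the point-at-target vector $y_t$ and
reports $\tfrac12 (D_{11}+D_{22}) / \bar\sigma_\epsilon$. We use a target
fSNR of 2.0 (mean across hands), which yields held-out single-bin decoding
correlations around 0.7–0.8 — the operating regime of a usable BCI decoder.
The per-hand values straddle the target (the left hand's weaker tuning gives
it a lower fSNR at the shared $\sigma$), matching the asymmetry seen in
recordings.

## Cross-validated tuning statistics

Squared norms and correlations of *estimated* coefficient vectors are biased
by estimation noise: the naive squared norm of a noisy vector overestimates
the true squared norm by the noise variance. `fit_encoding_cv()` fits the
tuning model by OLS separately on k disjoint trial folds, and
`cv_vector_stats()` estimates the squared magnitude as the average inner
product between fold estimates — unbiased under additive zero-mean noise,
because the noise is independent across folds. Correlations divide a
cross-fold inner product of channel-centered columns by the cross-validated
norms. These estimators can legitimately return negative squared norms or
correlations outside [−1, 1] at high noise; raw values are passed through.

Two practical choices:

* **Fold assignment is trial-level** (bins within a trial share the noise
  and the direction, so bin-level folds would leak), stratified by context
  and wedge, with globally balanced fold sizes.
* **Fold count trades bias for variance.** The estimators are unbiased at
  any k, but per-fold estimation noise grows with k (each fold has 1/k of
  the data) and the variance of the pooled statistic grows with it. On
  40-trial-per-type sessions we default to k = 3 and average the statistic
  over a few fold assignments (`tuning_report(n_repeats = )`); the full-scale
  setting of k = 5 is the default of `fit_encoding_cv()` itself.

`suppression_ratio()` (bimanual over unimanual mean x/y cv-magnitude per
hand) and the uni↔bi cv-correlations recover the programmed population
structure (0.66/1.0 suppression, 0.45/0.85 correlation) on a 192-channel,
40-trials-per-type session at calibrated noise.

`dpca_marginal_variance()` quantifies the laterality code: the
trial-averaged channel × laterality × direction-quadrant × time tensor is
decomposed additively into time, laterality, direction and interaction
marginalizations (condition factors absorb their interaction with time, as in
standard demixed PCA), and each factor's variance is estimated without
trial-noise bias by split-half cross-validation — the two halves'
marginalizations are element-wise multiplied and summed, so pure noise
contributes zero in expectation rather than inflating every factor. Negative
cross-validated components (possible by construction) are floored at zero
before fractions are formed; signed values are also reported. Directions are
quantized to quadrants on half-open intervals ([0°, 90°), …), matching the
electrode-level ANOVA grouping; ties on the axes are therefore deterministic.

## Decoders

* **Ridge** (`train_ridge()`): closed-form, penalty selected on a grid by
  k-fold CV maximizing mean held-out Pearson r, folds stratified so
  unimanual-right and -left time steps are balanced.
* **FFN** (`train_ffn()`): one densely connected hidden layer (512
  rectified-linear units at full scale; desk-scale experiments use 128–256)
  with a linear readout, trained by minibatch Adam on squared error with L2
  weight decay. The default decay (5e-3) was set for desk-scale convergence:
  it brings the FFN to parity with ridge in the linear regime
  (ρ = 0, no laterality) instead of overfitting channel noise, without
  capping its nonlinear advantage.
* **GRU** (`train_rnn()`): a day-specific affine input transform
  (identity-initialized; synthetic experiments use a single day), one GRU
  layer, a continuous head for the four cursor velocities and a discrete
  softmax head over {unimanual right, unimanual left, bimanual,
  no movement}. The loss is squared velocity error + cross-entropy + L2, at
  1:1 continuous-to-discrete weight by default (the relative weight is a
  config field). The discrete head *gates* the velocities at inference:
  per-bin argmax, a cursor only moves when its context class is active, with
  no hysteresis (optional smoothing deliberately off by default). We treat
  the four softmax classes as including the null class explicitly.
  Training-time input augmentations: i.i.d. input noise and a per-snippet
  random channel offset ("mean drift" — emulating slow nonstationarity in
  recordings). All three decoders are bit-reproducible given their seeds,
  and the GRU backward pass is verified against finite differences in the
  test suite.

Optimizer settings (Adam, batch sizes, step counts) are desk-scale defaults
tuned only for convergence on the synthetic problem sizes below, and are all
exposed in the configs.

## The simulation sweep

`run_laterality_sweep()` reproduces the decoder comparison across the
(ρ, laterality-size) grid: per cell, sample a population, generate a
balanced unimanual dataset, calibrate σ to fSNR 2.0, train ridge and FFN on
identical data, and evaluate held-out r and cursor jitter (rest-period speed
over move-period speed of the cursor that should be still). The expected
structure: ridge degrades monotonically in ρ regardless of laterality
(which it cannot use); the FFN holds its performance at high ρ when the
laterality dimension is large, and its jitter stays low — it uses laterality
to tell the hands apart. Removing the fitted laterality dimension
(`remove_laterality()`, projection onto the fitted $b_{lat}$ column
subtracted from every bin) erases the FFN's advantage but leaves ridge
unchanged.

The grid values are our choice (none are printed for the original
experiment): ρ ∈ {0, 0.25, 0.5, 0.75, 0.9, 1.0} × lat ∈ {0, 0.25, 0.5, 1.0}
at full scale, and a 3 × 3 sub-grid (ρ ∈ {0, 0.5, 0.9}, lat ∈ {0, 0.5, 1})
at one seed for the routine checks. Cells use 250 trials per hand (5,000
movement-window bins per hand) rather than the full 2,000 — the comparison's
qualitative structure is unchanged at this size and a full sweep then fits
in minutes on one CPU.

## Training-data augmentation

Stereotyped delay–move–idle calibration data lets a recurrent decoder
overlearn the task's temporal structure. `assemble_snippets()` fractures it:
clips of raw stream (0.2–0.8 × the 10-s snippet length, the bound applied to
the raw clip *before* dilation), each linearly interpolated in time by a
factor drawn uniformly from [0.5, 2], are appended in random order into
fixed-length snippets. Context class labels are resampled by nearest
neighbor (class identities cannot be interpolated); velocities are
interpolated like the inputs and deliberately *not* rescaled by the dilation
factor (values are resampled, not re-differentiated). A candidate clip must
respect a running balance record: no condition's share may exceed its target
(uniform over movement types, subdivided uniformly over direction quadrants
and the no-movement subtypes: per-type delay periods and rest) by more than
the tolerance (10%). Clips that merely *dilute* an over-represented
condition remain acceptable — otherwise the record can deadlock early.
Clips may span trial boundaries (fracturing structure is the point); a flag
forbids it. The final clip of a snippet is truncated to land exactly on the
snippet length, keeping the draw process unbiased. Every snippet records
its clip list, and `replay_snippet()` reproduces it bit-exactly.

Train and validation snippets are drawn from disjoint trial pools
(`split_pools()`), so augmented training data never overlaps held-out data.

## The closed-loop task and what it shows

`run_trials()` closes the loop without a human: each 20-ms bin, a simulated
user points at the target (unit cursor-to-target vector per attended cursor,
zero inside the target and during a 200-ms reaction time), the intention is
encoded through the population with context-appropriate coefficients plus
noise, z-scored with the *training* statistics, decoded, gated, assisted,
and integrated. Dwell/timeout mechanics follow the task: both cursors must
dwell in their targets simultaneously for 500 ms, any exit resets the
timers, 10-s timeout. Error assistance attenuates the velocity component
orthogonal to the cursor-target line; push assistance adds a target-directed
vector scaled by the decoded speed; lock mode freezes the non-active cursor.
Defaults for unstated geometry: workspace [−1, 1]², target radius 0.15,
target distance 0.7, output gain 0.5 units/s (configurable — online gain was
hand-tuned in practice, and our comparisons sweep it).

The simulated user has two deliberately imperfect features, both
configurable: a *sequential* attention strategy for bimanual trials (attend
the cursor farther from its target, 3-bin hysteresis), and an AR(1) aiming
error (`intention_noise`, radians) that makes the pointed direction wander
so that successful control requires ongoing correction. Angular error is
measured on the decoded velocity *before* assistance within the 300–500 ms
ballistic window (the alternative — measuring realized displacement — mixes
assistance into the statistic). The decoder's hidden state persists across
trials by default, as a continuously running online decoder's would.

`run_augmentation_comparison()` ties it together: the same source session
trains a `rawRNN` (stereotyped consecutive snippets) and an `altRNN`
(augmented snippets); offline performance is compared on stereotyped
held-out data and online performance in the simulated closed loop. The
offline ordering — rawRNN at least as good as altRNN, since the stereotyped
decoder is free to exploit the trial cadence — reproduces robustly across
all regimes we examined. The *online reversal* (altered-data training
winning in closed loop) does **not** emerge under this generator, and the
reason is informative: the synthetic code is stationary and instantaneously
decodable at every bin, delay-period activity carries no preparatory signal
or observable go-cue timing, and the training labels are exact functions of
the encoded intention. A stereotype-trained recurrent decoder therefore has
nothing *harmful* to overlearn — its offline advantage is genuine signal
and transfers to the closed loop. Data alteration pays off precisely when
offline temporal regularities are deceptive (transient or nonstationary
tuning, preparatory activity a network can clock movements from,
systematic misalignment between prescribed targets and actual intention),
none of which this encoding model contains. The generator exposes a
`reaction_jitter` argument and the user an `intention_noise` argument to
explore mild versions of such mismatches; both default to off.

## Desk-scale problem sizes

Checks in this package run at reduced sizes chosen once: 96–192 channels,
30–64 trials per type for tuning analyses, 250 trials per hand per sweep
cell, GRU width 128 (full scale 512), 5-s (250-bin) snippets, and a few
hundred training batches. Full-scale settings (2,000 trials per hand, 512
units, 10-s snippets, 2,000 snippets) are plain parameter changes.

## Known limitations

* The noise model is i.i.d. Gaussian with one shared σ — no Poisson
  statistics, shared low-dimensional noise, or electrode-array geometry; the
  fSNR calibration absorbs the first-order consequences for decoding but not
  correlated-noise effects on the population statistics.
* The synthetic laterality code is exactly constant within a context;
  recordings presumably carry a noisier, time-varying code.
* Delay-period activity is baseline plus noise (no preparatory tuning), so
  the no-movement subtypes differ only in their balance-accounting role, not
  in their neural content.
* The simulated user is not a learning agent: findings about decoder
  *adaptation* across sessions are out of reach by construction.
* `reanalyze_deposited()` expects sessions already converted to this
  package's plain-text layout; it never fetches data.
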