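---
title: "Collaborative adversarial learning for CGM forecasting: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative adversarial learning for CGM forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmforecast)
```

## The forecasting problem

Continuous glucose monitors report blood glucose every 5 minutes in the
40–400 mg/dL sensor range. Short-horizon forecasting — 30 or 60 minutes
ahead, i.e. 6 or 12 steps — supports anticipatory treatment decisions in
type 1 diabetes. The task is univariate and subject-specific: a model is
trained on the first weeks of one person's CGM stream and evaluated on that
person's later, held-out days.

`cgmforecast` frames this as supervised sequence-to-sequence learning. A
window of `n` history samples (`Hx`, default 12 samples = 60 min) is mapped
to the `m`-sample prediction horizon (`PHx`). The window immediately after
the horizon — the *post-horizon* window `PPHx`, by construction equal in
length to the horizon — is never predicted at deployment, but two of the four
training frameworks use it as a supervision signal.

## The four frameworks

All four share the same *primary regressor* `PR`: a multilayer perceptron
with a 50-unit and a 20-unit dense hidden layer and an `m`-unit output layer,
ReLU activations throughout. The frameworks differ only in which auxiliary
components shape its gradients:

| framework | auxiliaries | system loss |
|---|---|---|
| IL | none | `LS = LP` |
| AL | discriminator | `LS = LP + LA` |
| CL | auxiliary regressor | `LS = LP + LC` |
| ACL | both | `LS = LP + LA + LC` |

with unweighted components (deliberately no per-framework loss tuning, so
differences are attributable to the learning strategy):

- `LP = E(PR(Hx), PHx)` — the predictive loss; `E` is the mean squared error.
- `LA` — the adversarial term. The *auxiliary discriminator* `AD` (a 1-D CNN:
  20-filter and 10-filter convolutions, kernel 3, stride 1, no padding, ReLU,
  then a single sigmoid unit) scores full sequences of length `n + 2m`. It is
  trained with binary cross-entropy to label real sequences
  `(Hx, PHx, PPHx)` as 0 and predicted sequences `(Hx, PHx^, PPHx)` as 1.
  The regressor's term applies the shared error functional to the score,
  `LA = E(AD(Hx, PHx^, PPHx), 0)` — it is rewarded when its predictions are
  scored as real (see *Numerical choices* for why the squared-error form is
  used on the score).
- `LC = E(AR(Hx + PHx^), PPHx)` — the collaborative term. The *auxiliary
  regressor* `AR` (same MLP architecture, input width `n + m`) forecasts the
  post-horizon window from the history concatenated with the *predicted*
  horizon. Crucially, this loss is backpropagated through `PHx^` into the
  primary regressor: horizon predictions are shaped to remain informative
  about what follows them, which is the mechanism that distinguishes CL/ACL
  from simply extending the horizon.

Each minibatch performs one discriminator step on its own loss (AL/ACL),
then one joint Adam step on the regressor objective; the auxiliary regressor
receives its `LC` gradient within that joint step. Defaults follow the common
optimisation setting: Adam, 600 epochs, batch 128, learning rate 0.002, with
every repeat seeded. Deployment uses `PR` alone.

The package exposes the training mechanics for inspection:
`train_system(..., block_collab_gradient = TRUE)` severs the gradient path
through `PHx^` (the auxiliary regressor still learns, but no longer shapes
the primary one), and `detach_auxiliary = TRUE` removes all auxiliary
influence, which provably collapses any framework's primary-regressor
trajectory onto IL's under the same seed — both are asserted in the test
suite.

## Preprocessing

*Imputation.* Training-side gaps are filled by linear interpolation between
the flanking observed values. Held-out data must not see the future, so
test-side gaps are filled causally: each missing sample extends the straight
line through the two most recent (observed or already-imputed) samples,
clipped to 40–400 mg/dL. The two-point anchor is the minimal linear
extension; the anchor width is not prescribed by the method, and wider
anchors would smooth but also lag. When a held-out period begins inside a
gap, the experiment driver anchors the extension on the last training
samples.

*Reframing.* A window of length `n + m` (+ `m` with post-horizon targets) is
rolled over the fully imputed series with stride 1 (the densest reading of a
rolling window); the sample count is `floor((L - n - m - [post]·m)/stride) + 1`,
verified against brute-force enumeration in the tests. Windows containing
imputed values are kept — imputation precedes reframing with no exclusion
rule. All four frameworks train on identical window sets (IL simply ignores
the post-horizon targets), removing sample-count confounds from the
comparison.

*Scaling.* Because every regressor layer is ReLU — including the output
layer — the networks can only emit non-negative values, so targets are
min-max scaled to [0, 1] per subject using training data only. The transform
is affine and unclamped: test values outside the training range map outside
[0, 1], and predictions are mapped back to mg/dL before evaluation.

## Evaluation

Mathematical metrics are RMSE, MAE, MAPE (in percent) and the coefficient of
determination r² (reported ×100). Clinical metrics are the surveillance
error (SE) of each (reference, prediction) pair with its banding — below 0.5
no clinical risk, then slight/moderate/high at 1.5/2.5/3.5, extreme above —
summarised as the average SE (ASE) and the percentage of predictions with
SE < 0.5; and the Matthews correlation coefficient of adverse-event
detection, where an adverse event is glucose strictly below 70 mg/dL
(hypoglycaemia) or strictly above 180 mg/dL (hyperglycaemia), boundary
values counting as euglycaemia. When the confusion matrix has an empty
margin the MCC is reported as undefined (`NA` with a reason) rather than
coerced to zero.

Metrics are computed on the horizon *endpoint* of each test window by
default — the standard convention for glucose-forecasting error tables; an
`"all"` timepoint option scores every predicted step instead, since the
convention is not universal.

The default SE surface is an analytic approximation: `SE = s·|log(pred) -
log(ref)|` with `s = 4.5/log(10)`, which is zero on the diagonal, increases
monotonically with relative error, weighs a given absolute error more
heavily in the hypoglycaemic range, and reaches the extreme-risk ceiling
(4.5) at the largest possible mismatch of the sensor range. The consensus
surveillance-error grid is a digitised survey surface that is not
redistributable here; `surveillance_error()` therefore accepts a
user-supplied grid table and interpolates it bilinearly, and every clinical
report records which surface produced it. Absolute ASE values from the
analytic surface are consistent in ordering but not numerically identical
to consensus-grid values.

## Model comparison

Competing systems are compared per *block* — one block per (scenario ×
metric) combination, where a scenario is one subject at one horizon. Within
each block the systems' mean-over-repeats values are ranked, 1 best, ties
receiving average ranks; metric orientation (lower-better for RMSE, MAE,
MAPE, ASE; higher-better for r², MCC, %SE<0.5) is applied before ranking.
The global null of identical performance is tested with the Friedman
chi-square approximation with tie correction (verified against
`stats::friedman.test` on randomised tables); pairwise follow-up uses the
Nemenyi test from the studentised-range distribution, with the critical
difference `CD = q(α,k)·sqrt(k(k+1)/(6N))`, alongside Holm–Bonferroni
adjusted decisions, both reported because practice varies.
`cd_diagram_data()` and `plot_cd_diagram()` produce the standard
critical-difference diagram.

The packaged benchmark summary (`ohio_benchmark_results()`) holds the
published per-scenario mean metrics of the four frameworks on the two Ohio
T1D cohorts (12 subjects × 2 horizons × 7 metrics = 168 blocks). Ranking it
reproduces the published average ranks — ACL ≈ 2.14/2.18, CL ≈ 2.22/2.25,
AL ≈ 2.49/2.52, IL ≈ 3.04/3.06 (published/recomputed) — with the tie rule
being the one assumption; the Friedman test rejects at the 5% level and the
critical difference for k = 4, N = 168 is ≈ 0.36.

## The synthetic-data generator

Access to the Ohio T1D cohorts requires a data-use agreement, so the package
ships a simulator whose output is statistically Ohio-like without being
derived from the data. A series is the sum of:

- a basal level (default 150 mg/dL) with a day-scale random drift
  (SD 20 mg/dL, daily knots, linearly interpolated);
- a sinusoidal circadian component (amplitude 25 mg/dL);
- meal excursions: a Poisson number per day (rate 3), uniform onset times,
  gamma-shaped pulses peaking 45 min after onset with peak heights uniform
  in 60–150 mg/dL and ~5 h of support;
- a stochastic excursion process with *level* persistence 0.98 and *velocity*
  persistence 0.85 (an AR(1) on the rate of change cascaded into an AR(1) on
  the level — equivalently an AR(2) with real roots), stationary SD
  35 mg/dL;

clipped to 40–400 mg/dL. Sensor dropout is simulated separately as
contiguous gaps with geometric lengths (mean 6 samples) placed until a
target missing fraction is reached within ±2 percentage points, never
masking the series endpoints so imputation anchors exist.

The velocity-persistent noise deserves a note. Plain AR(1) jitter at
CGM-realistic variance produces 5-minute steps of 7–15 mg/dL — far rougher
than real traces, whose consecutive-sample changes are a few mg/dL and whose
trends persist for tens of minutes (the familiar "trend arrows"). Roughness
matters twice: it makes the persistence baseline nearly unbeatable at short
horizons (no learnable trend), and it makes smooth regressor outputs
trivially separable from real sequences, destabilising adversarial training.
The defaults were therefore calibrated once against published anchors of the
real benchmark: subject means within 135–215 mg/dL (simulated 56-day mean
≈ 172), SDs within 45–70 (≈ 55), nonzero hypo- and hyperglycaemic rates
(≈ 2% / ≈ 40%), and a naive persistence endpoint RMSE at the 30-min horizon
of ≈ 27 mg/dL against a published ≈ 28.

What the simulator does **not** emulate: insulin and meal covariates (no
physiology), sensor calibration artefacts and drop-to-40 compression lows,
day-of-week structure, and the heavy-tailed missingness of some real
subjects. Passing the package's synthetic-data tests therefore demonstrates
that the training mechanics and statistics work as specified — not that any
framework attains its published real-data error levels.

## Numerical choices

- *Generator-side adversarial functional.* The discriminator itself is
  trained with binary cross-entropy. For the regressor's `LA`, the package
  applies the same squared-error functional `E` used by `LP` and `LC` to the
  discriminator score: `LA = mean(AD(fake)²)` toward the real label 0 (the
  formal real-sequence term `E(AD(PHx), 1)` carries no regressor gradient
  and is omitted). The practical reason is gradient saturation: a
  deterministic regressor cannot mimic sensor-noise texture, so a
  sufficiently expressive discriminator eventually classifies confidently;
  under a cross-entropy generator loss the gradient magnitude is then at its
  maximum and empirically destroys the predictive fit (up to dead-ReLU
  collapse of entire output units), whereas under the squared-error form the
  gradient vanishes in the same regime and the adversarial signal acts
  mainly in early training — matching the published behaviour in which AL
  tracks IL closely instead of diverging.
- *Weight initialisation* is seeded Glorot-style uniform. Biases start
  positive (hidden 0.1, output 0.5 — the midpoint of the scaled target
  range): with ReLU on the output layer, a unit whose pre-activation goes
  negative for every training sample receives no gradient and is
  irreversibly dead; frozen all-zero output columns were reproducible
  without the positive margin.
- *Discriminator geometry*: "20-unit/10-unit" convolutions are read as
  filter counts; kernel 3, stride 1, no padding, no pooling — the minimal
  nontrivial choices, recorded in the built model.
- *Update order*: discriminator first, then the joint regressor step, within
  every batch; batches are reshuffled each epoch from a dedicated seeded
  stream so all frameworks consume identical shuffles under a shared seed
  (this is what makes the detachment-nesting test exact).
- *Ties in ranking* use average ranks; the Friedman statistic uses the
  chi-square approximation with tie correction (not the F refinement).
- *Degenerate inputs*: imputation requires observed series endpoints
  (training side) or two observed samples before the first gap (test side);
  the scaler rejects constant training data; the Friedman test returns
  statistic 0 and p = 1 when every block is fully tied; probabilities are
  clamped away from {0,1} by 1e-12 inside training for finite losses.

## Scaled problem sizes

The full published protocol (six subjects per cohort, two horizons, ten
repeats, 600 epochs) is hours of compute. The package's own experiments and
tests run a scaled design chosen to keep the complete suite in minutes on
one CPU while preserving every mechanism: a 14-day synthetic subject with a
3-day hold-out, 100 epochs, and three repeats per framework, at the 30-min
horizon with the 60-min history. Under those conditions each framework's
mean endpoint RMSE beats the naive persistence baseline, and a single
training run takes well under ten minutes. The `experiment_config()` /
`run_experiment()` driver exposes the full-scale settings (600 epochs, ten
repeats, 46/10-day split) as plain arguments.

## Known limitations

- The MLP backbone is deliberately lightweight; recurrent or attention
  backbones are out of scope, as is multivariate conditioning.
- The simulator's realism bounds what synthetic experiments can show (see
  above); published per-subject table values are not reproducible without
  the access-restricted cohorts.
- The analytic SE surface approximates the consensus grid's banding, not its
  exact values.
- Adversarial training remains seed-sensitive at small epoch budgets even
  with the saturating loss; repeated-run means are the supported comparison
  unit, as in the published protocol.
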