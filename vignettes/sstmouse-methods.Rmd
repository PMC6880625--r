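---
title: "Models and methods behind sstmouse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sstmouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstmouse)
```

# The task and the measures

`sstmouse` simulates and analyses a stop-signal task (SST) in which the go
response is either a keypress or a continuous mouse reach toward one of two
response buttons. A session has 576 trials, 432 go and 144 stop (25% stop
trials). The go stimulus is a random-dot kinematogram whose coherence (10,
50 or 80% of dots moving together) sets the difficulty of the direction
judgement. On stop trials an auditory stop signal follows the go stimulus
after a stop-signal delay (SSD). Two SSD regimes are provided as named
profiles:

* **`exp1`** — SSDs drawn uniformly from the presets 100–600 ms;
* **`exp2`** — an adaptive staircase: SSD starts at 600 ms and moves ±50 ms
  after each successful/failed inhibition, tracking the 50% inhibition point.

Feedback scoring awards +100 points for a correct go response or a
successful inhibition and −50 for any incorrect response; a go trial without
a response earns −50, since no direction was indicated (the scoring rule for
omissions is our choice; only responses are described by the task rules).
Participants are retained only with at least 5% successful inhibition and at
least 5% correct direction indication (both inclusive).

## Reactive inhibition: integration-method SSRT

The stop-signal reaction time (SSRT) is estimated by the integration method.
The go RTs are rank-ordered and the *k*-th smallest is taken as the stop
process's finishing time, with *k* = ⌈*p* · *n*⌉ and *p* the observed
proportion of responding on stop trials — e.g. with *p* = 0.55 the finishing
time is the 55th percentile of the go RTs. Under preset SSDs, a finishing
time is estimated at each SSD level from that level's *p*, the SSD is
subtracted, and the per-level estimates are averaged (unweighted). Under the
staircase, the overall finishing time minus the mean SSD over all stop
trials gives the estimate.

Numerical conventions worth stating:

* the order statistic uses nearest-rank with ceiling (no interpolation), as
  the "n-th go RT" phrasing implies, with a 1e-9 slack inside the ceiling so
  that a product like 0.55 × 100 is not pushed to rank 56 by floating-point
  representation;
* a per-level *p* of exactly 0 or 1 leaves that level's estimate undefined;
  such levels are dropped from the average and counted (attribute
  `dropped_levels`) rather than producing unbounded estimates;
* go RTs entering the finishing time are responded go trials only; treating
  omissions as maximal RTs is deliberately not implemented;
* per-coherence SSRT pairs stop trials at a coherence with go RTs at the
  same coherence.

## Kinematic measures

For mouse sessions the per-trial trajectory (sampled nominally every 16 ms)
yields: total path length (sum of Euclidean distances between consecutive
samples; rest contributes zero), maximum velocity (largest segment distance
over recorded time difference), maximum acceleration (largest absolute
change between adjacent segment speeds over the time between segment
midpoints), movement initiation time (first sample whose cumulative path
from the start exceeds 0.01 screen units — the threshold is our choice) and
movement time (initiation to click, or to trial end without a click).

The stopping distance Δ of a stop trial is the path length after
stop-signal onset, Δ = d~total~ − d~before~; the sample segment straddling
the signal is split proportionally in time. Δ is averaged per SSD level
first and the per-level means are then averaged (Δ~average~), so levels with
fewer trials are not down-weighted.

All measures are computed on the raw timestamped samples using recorded
timestamps (robust to dropped frames). The 101-timestep time normalization
(`resample_trajectory()`) is available for export and plotting but is not
used for the measures: linear resampling shortens paths and distorts
velocities.

# The generative model

## Latent traits

Each simulated participant carries two standard-normal latent traits,
impulsivity and inattention, correlated at 0.3 by default. Monotone
(log-linear or logistic) links map traits to task parameters: impulsivity
raises peak reach speed and weakens braking deceleration (lengthening the
post-signal travel); inattention inflates go-RT dispersion and the
attentional lapse rate. Questionnaire subscales C, F (impulsivity-loaded)
and A, E (inattention-loaded) are linear combinations of the traits plus
Gaussian noise scaled for a reliability of 0.8, reported on a T-score scale
(mean 50, SD 10). The `null` scenario zeroes all loadings, making scores
pure noise — the calibration condition.

## The race

Going and stopping race independently. In **keypress** mode the go finishing
time *G* is lognormal (median 650 ms at the easiest coherence, 35% relative
slowing per unit coherence below 0.8, σ = 0.22 on the log scale); the stop
process finishes at *S* = SSD + SSRT, and a stop-trial response is emitted
iff *G* < *S*. The true SSRT averages 250 ms (SD 30 between participants).
Direction accuracy is logistic in coherence (about 0.63 / 0.94 / 0.99 at
10/50/80%).

In **mouse** mode the overt go process is a reach: movement initiation
(~300 ms ± 80 within participant), then a symmetric sine-squared speed
profile toward the chosen button (peak 3.6 screen-units/s at baseline,
per-trial lognormal variation). If the stop process finishes before button
contact, braking at constant deceleration (15 units/s² at baseline) begins
at *S* and the cursor halts after *v(S)²/2a*; the trial still counts as a
response if the cursor coasts into the button. The baseline speed and
braking values were anchored to the task's stated design fact that SSD
600 ms corresponds to roughly 50% stop accuracy (that is why the `exp2`
staircase starts there): at those values the deterministic braking margin
reaches zero when the stop process finishes near 850 ms = 600 + 250.

Inhibition-failure criteria: keypress — any keypress; mouse under `exp1` —
a button click; mouse under `exp2` — the cursor crossing 25% of the
vertical start-to-button distance at any sample.

Trajectories get small isotropic Gaussian jitter (SD 0.002 screen units)
applied **only to samples where the ideal cursor moved**; a resting cursor
is reported at constant coordinates, as an operating-system pointer stream
would report it. Jittering rest samples too would add roughly half a screen
unit of spurious path length over the long stationary tail of a successful
stop trial, swamping the stopping distance; "no movement contributes zero
distance" only holds if rest is recorded as rest.

What the generator does **not** emulate: trajectory curvature or
change-of-mind excursions (paths are straight in expectation), RT
distributions beyond the lognormal convention, context effects between
trials, fatigue, or the psychometrics of the real questionnaires. Passing
tests therefore demonstrate that the estimators recover the quantities this
model defines — not that real data share the model's distributional forms.

# Association and prediction analyses

Spearman's ρ uses average ranks for ties and a two-sided p-value from the
t approximation with n − 2 degrees of freedom (sidedness is our choice).
BH false-discovery-rate control at q = 0.05 is applied within one printed
table (one family per table: overall and each coherence level), matching
per-table significance flags. The two-sample Kolmogorov–Smirnov p-value
uses the asymptotic Kolmogorov distribution at √n~eff~·D with
n~eff~ = n~x~n~y~/(n~x~+n~y~); exact small-sample p-values are out of
scope. Undefined feature cells (e.g. SSRT at a boundary response
proportion) are dropped pairwise per correlation.

## Ridge with nested cross-validated bootstrap

Prediction of a subscale from the feature vector uses ridge regression with
predictors standardized to mean 0, SD 1, the standardization always learned
from the training rows of the split at hand. The penalty λ is chosen on a
grid of 60 log-spaced values in [10⁻⁴, 10⁴] (the grid is our choice) by
10-fold CV minimizing mean squared prediction error, taking the smallest λ
on ties (least shrinkage at equal error).

Evaluation runs 10-fold CV nested inside 5-fold CV with bootstrap
resampling: each of the 1000 replicates resamples participants with
replacement, splits into 5 outer folds, selects λ by inner CV on the outer
training rows only, fits there and predicts the outer test rows. Two
numerical choices matter and were made deliberately after measuring their
alternatives on null data:

* **Folds are assigned at the level of original participants**, so all
  bootstrap copies of a participant land on one side of every (outer and
  inner) split. Letting copies straddle folds lets the model memorize test
  rows: on pure-noise outcomes (n = 50) the straddling variant returns a
  median ρ near +0.4 instead of 0.
* **Each replicate's ρ is the mean of per-outer-fold Spearman correlations**
  rather than one correlation over pooled predictions. Pooled predictions
  carry a fold-mean artifact: under heavy shrinkage the prediction is
  nearly the training-fold mean, which is conditionally anti-correlated
  with its test fold's values, biasing the pooled ρ to about −0.2 under the
  null. Per-fold correlation is invariant to per-fold constants and
  calibrates to ≈ 0 under the null while still reaching > 0.99 under a
  noiseless linear signal.

The report gives the median and the raw median absolute deviation (no
consistency constant) of the replicate correlations; replicates whose test
outcomes are constant are recorded as missing, never silently dropped.

Because a single null dataset retains its chance feature–score sample
correlations (spread of roughly ±0.15 in the per-dataset median ρ at
n = 50, however many bootstrap replicates are run), calibration checks
aggregate over several seeded null datasets rather than trusting one.

# Problem sizes used by the test suite

The packaged checks run at sizes chosen to exercise the statistics without
waste: SSRT recovery uses the full 576-trial sessions over 200 replicates
per condition; staircase tracking uses 1000 stop trials; association and
prediction calibration use 50-participant studies with 96-trial sessions;
the planted-effect check uses 500 participants with 72-trial sessions.
Session length enters those last checks only through the per-participant
noise of the feature estimates, so shorter sessions trade statistical
sharpness, not validity; the planted effects are comfortably detectable at
these sizes.

# Known limitations

* The continuous (mouse) SSRT in the `exp1` profile is defined by click
  responses, which are rare at short SSDs; many per-SSD levels are dropped
  at realistic parameters, and the resulting estimate measures the click
  race, not the latent 250 ms stop latency. The stopping distance is the
  measure designed for that regime.
* The staircase's SSD bounds are clamped to [0, response window − stop-tone
  duration] so the tone always fits inside the trial; the task description
  names no bounds.
* Balance of coherence × direction cells is enforced within each trial type
  independently; whether the original task balanced coherence within stop
  trials is not documented.
* `ks_two_sample()` is asymptotic; with very small samples its p-values are
  approximate (the D statistic is exact).
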