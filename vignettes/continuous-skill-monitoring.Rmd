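---
title: "Continuous bimanual skill monitoring: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous bimanual skill monitoring: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bimanual psychomotor skill in surgery unfolds in time: a performer can
operate at expert level for minutes and then drift into unsafe force levels
or uncontrolled bleeding for a few seconds. Summative end-of-task scores
hide this structure. `surgskill` implements a continuous assessment
pipeline: raw two-instrument simulator recordings (an ultrasonic aspirator
in the dominant hand, a bipolar forceps in the non-dominant hand, sampled
every 0.02 s) are reduced to sixteen interpretable performance metrics on a
0.2 s grid, and a recurrent regression model emits an expertise score five
times per second, anchored at +1 (expert) and −1 (novice) but deliberately
unclipped beyond that range. The same architecture, run in reverse, yields
per-metric coaching targets and bleeding / tissue-injury risk trajectories.

Because the original simulator cohort is not publicly distributable, the
package ships a synthetic bimanual-motion generator with a ground-truth
skill parameter. All quantitative claims in the test suite are claims about
this generator, not about real operative data; see *What the synthetic
cohort does and does not show* below.

## The assessment model

Each trial is a variable-length sequence $x_{1:T} \in \mathbb{R}^{16}$ of
z-scored metrics at 0.2 s steps. The model is a sequence-to-sequence
regressor

> input → LSTM($H$) → dropout → LSTM($H$) → dropout → dense(1) → MSE,

with both LSTM layers unidirectional and $H = F + 1 = 17$ hidden units for
$F = 16$ input metrics — a deliberately small network sized by the
features-plus-one rule. Training targets are constant label sequences:
every timestep of an expert trial is labelled $+1$, of a novice trial $-1$.
The loss is the mean squared error pooled over all timesteps of all
sequences in a minibatch, so a trial's length does not change its
per-timestep weight. At inference the dense output is reported untouched;
scores outside $[-1, 1]$ are meaningful ("more expert-like than the average
training expert") and never clipped.

Optimization is Adam with learning rate
$\eta(e) = 10^{-3} \times 0.1^{\lfloor (e-1)/25 \rfloor}$, i.e. a tenfold
decay every 25 epochs, minibatches reshuffled every epoch, and a minibatch
size equal to the number of training trials divided by the repeats each
participant performs (108 trials / 6 repeats = 18 at full scale). The full
schedule is 1000 epochs; the scaled-down studies in this package use 100
(see *Problem sizes* below). RMSE is monitored on the training and
validation folds every epoch and on the test fold once at the end.

Data are split 70/15/15 **by participant**: all trials of one individual
stay in one fold, because trials of the same person are strongly dependent
and leaking them across folds would inflate validation performance.
Assignment is greedy on a seeded shuffle of participants, each going to the
fold furthest below its target trial count, so realized fold sizes can
differ from the targets by up to one participant block.

### Numerical and design choices

* **Dropout rate 0.2** after each LSTM layer. Only dropout's presence and
  purpose are fixed by the design; 0.2 is the conventional default and is
  configurable.
* **Variable-length minibatches** are handled by per-sequence gradient
  accumulation with the batch loss normalized by the batch's total timestep
  count. This is numerically identical to padding to the batch maximum and
  masking padded steps out of the mean, without padding arithmetic.
* **Weight initialization**: uniform $\pm 1/\sqrt{H}$, forget-gate bias 1
  (the standard trick to keep early memory open); all randomness (init,
  shuffling, dropout masks) is drawn from R's RNG so a single seed makes
  training bit-reproducible.
* **No gradient clipping by default**; a `clipnorm` switch exists for
  divergence rescue. A non-finite loss aborts training with the epoch
  index.
* **Z-score convention**: population standard deviation (divide by $n$),
  fixed so that re-standardizing the pooled training rows gives exactly
  mean 0, sd 1 and the transform round-trips to $10^{-10}$. A metric that
  is constant over the training pool raises an error naming the metric
  rather than silently dividing by zero.

## The sixteen metrics

Ten metrics follow directly from the recorded channels: inter-tip
separation distance; applied force, tip speed and tip acceleration per
instrument; tumor volume removed; blood volume present; and cumulative
healthy-tissue damage. The remaining six are reconstructed from the five
standard performance categories (safety, quality, efficiency, bimanual
cognitive, movement) and flagged `reconstructed` in the manifest: path
length and pedal-active fraction per instrument, bleeding rate, and the
inter-tip relative-velocity magnitude. The exact metric set used on the
original platform is not recoverable from public sources; the pipeline is
parametric in the manifest so the set can be swapped without touching the
model code.

Window semantics are fixed as half-open $[t, t+0.2)$ windows starting at
the first raw timestamp, with a trailing partial window dropped. Velocity
is the first difference of tip position at raw resolution (first sample 0),
acceleration the first difference of the velocity vector, both
window-averaged as magnitudes. Cumulative channels (tumor, damage) enter as
end-of-window deltas rather than running totals so that features are
roughly stationary in trial time — constant per-timestep labels presuppose
roughly stationary inputs. Raw streams are first linearly interpolated onto
an exact 0.02 s grid (activation channels carry the last earlier sample),
which preserves monotone channels.

## The synthetic cohort

The generator produces what the pipeline needs and nothing more: 50 Hz
streams whose statistics separate monotonically in a latent skill
$s \in [-1, 1]$.

* Tip trajectories are discrete Ornstein–Uhlenbeck processes around slowly
  wandering targets; the innovation scale $4.0 - 1.6s$ mm/√s makes motion
  smoother, slower and shorter-pathed as skill rises.
* Forces are nonnegative mean-reverting processes with mean
  $1.2 - 0.5s$ N (aspirator) and $0.9 - 0.35s$ N (bipolar).
* Pedal activation is an alternating-renewal process whose on-fraction
  rises with skill (0.55 + 0.20 s aspirator, 0.35 + 0.15 s bipolar).
* Bleeding and healthy-tissue damage are Poisson event processes with
  intensity $\propto (1 - 0.6s)$; blood volume decays faster while the
  aspirator is active; tumor removal follows
  $\dot T = r(1+0.7s)\,\text{active}\,(1-T)$, hence stays in $[0,1]$ and
  nondecreasing.
* Mean inter-tip distance narrows with skill ($8 - 3s$ mm), reflecting
  closer bimanual coordination.

Every map is affine in skill, and `skill_directions()` publishes the
resulting sign of each metric's skill dependence so tests can assert all
sixteen directions. Trial durations are drawn uniformly (default 90–180 s;
the reduced studies use 60–120 s) to force variable-length sequence
handling. Cohort designs mirror the reference study: 14 experts + 12
novices × 6 trials (156 development trials), 14 seniors + 10 juniors × 6
(144 trainee trials), with group skill distributions
N(0.8, 0.1), N(0.33, 0.15), N(−0.33, 0.15), N(−0.8, 0.1) truncated to
$[-1, 1]$ — the ±0.33 anchors match the risk-module level codes.

**What passing tests do and do not show.** The generator's metrics are
conditionally Gaussian-ish, stationary given skill, and separate cleanly;
real operative data have task phases, non-stationarity, sensor artifacts
and within-person variability that this generator deliberately omits.
Recovery of the synthetic skill ladder (Spearman ≥ 0.9) demonstrates that
the pipeline's mechanics — normalization, sequence training, scoring,
aggregation — are correct and that two-end training can interpolate a
continuum; it does not certify discriminative validity on real surgical
performance.

## Coaching and risk inversion

Five inverse models share the assessment architecture but swap the roles of
inputs and outputs: each predicts one target metric per timestep from the
remaining metrics plus a constant expertise channel, with the hidden width
again inputs + 1. Coaching models (aspirator force, bipolar force, tip
separation) force the expertise channel to 1 regardless of the performer,
producing the expert-level trajectory of that metric as a concurrent target
(output at $t$ revises the metric at the same $t$; no forecasting lag is
introduced). Risk models (bleeding, healthy-tissue injury) set the channel
to the user's level code — expert 1, senior 0.33, junior −0.33, novice −1,
a closed vocabulary — and return the predicted raw trajectory in original
units. A configurable post-step flags intervals where the user-level
prediction exceeds the expert-level prediction by a factor (default 2×).

One input-design choice is ours: the published input lists per inverse
model are not publicly available, so the default is all-metrics-minus-target
— except that a metric reduced from the same raw channel as the target is
also excluded (blood volume ↔ bleeding rate). Including the sibling would
let the model copy the bleeding signal from its near-duplicate, which both
constitutes leakage and silences the expertise channel, defeating the
purpose of level-conditional risk prediction. Coaching targets have no such
sibling and keep the full 15 + 1 input set.

Feedback models are trained on the two-end (expert/novice) pool only,
mirroring the assessment model's training data.

## Statistical validation harness

Scored cohorts are compared with the classical toolkit: participant
averages (mean of task averages over available trials — a missing trial is
simply absent, never imputed) enter a one-way ANOVA with Tukey–Kramer
honestly-significant-difference post hoc (chosen over plain Tukey because
group sizes are unequal), Shapiro–Wilk normality per group,
and a median-centered Levene (Brown–Forsythe) homogeneity test. Group means
carry t-based 95% confidence intervals (the CI method is otherwise
unspecified upstream). Trainee scores are regressed on year of training by
ordinary least squares, with fellows coded as year 7. Two degenerate-input
conventions are fixed: when the between-group sum of squares is zero at
working precision the ANOVA reports F = 0, p = 1 (rather than a 0/0
artifact), and a constant response reports slope 0, R² = 0, while a
constant *predictor* is an error.

## Problem sizes

The studies bundled with the package run at desk scale, chosen once as the
smallest sizes at which every property of interest is comfortably
resolved: oracle-equivalence fixtures use 2 s streams; unit-test cohorts
use 4 + 4 performers × 2 trials of 20–30 s with 15 training epochs; the
validation study uses 10 + 10 performers × 6 trials of 60–120 s, 100
epochs, five seeds, evaluated on a nine-level skill ladder and a
14/14/10/12 four-group cohort. The full-scale schedule (1000 epochs,
90–180 s trials, 26-participant development cohort) is the package default
for production use via `cmd_pipeline()`.

## Command-line interface

The shell entry point (`inst/cli/surgskill`) exposes the two orchestrators,
`simulate` and `pipeline`; the intermediate stages (extract, split, train,
score, coach, risk, validate) are exported functions that `pipeline` calls
and that scripts can compose directly, so they are not duplicated as
subcommands. Run configurations are YAML; every artifact is delimited text
with a JSON sidecar carrying the seed and a configuration hash, and
`pipeline --resume` reuses a stored model only when its hash matches.

## Known limitations

* The LSTM trainer is single-threaded CPU code sized for 17-unit models;
  it is not a general deep-learning engine.
* The generator has no task phases, no haptic or tissue physics, and no
  within-trial skill drift; scores on synthetic intermediate skills
  saturate toward the ±1 anchors faster than real trainee scores would.
* The reconstructed six metrics and the inverse-model input lists are this
  package's choices, flagged as such in the manifest, not claims about the
  original platform.
* Group-level statistics on synthetic cohorts are illustrations of the
  harness, not evidence about real expertise groups.
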