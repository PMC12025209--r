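---
title: "Methods: sEMG wrist-movement recognition and muscle-force estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG wrist-movement recognition and muscle-force estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristemg)
```

## The problem

Myoelectric control of a wrist rehabilitation robot needs two things from a
forearm surface-EMG (sEMG) armband: a reliable decision about *which* wrist
movement the wearer intends (flexion and extension over small or large
ranges, radial and ulnar deviation, or rest), and an estimate of *how much*
muscle force accompanies it, so resistance training can oppose the wearer
with a matched force. wristemg implements this pipeline end to end:
time-domain feature extraction, ReliefF feature selection, a
backpropagation neural network (BPNN) classifier, two layers of decision
post-processing, and static/dynamic linear force models — plus a synthetic
signal generator so everything is testable without hardware.

## The synthetic signal model

`generate_recording()` emulates an 8-channel armband. Each channel is
zero-mean Gaussian noise band-limited to 20–450 Hz (a second-order
Butterworth band-pass applied forward and backward), the band holding most
sEMG energy at a default 1000 Hz sampling rate. Amplitude carries all the
class and load information: channel $c$ during movement $m$ under load $L$
newtons is scaled so that

$$\mathbb{E}[\mathrm{MAV}] = A_{m,c}\,(\beta_0 + \gamma L),$$

where $A$ is the movement-by-channel activation profile, $\beta_0$ the base
amplitude (default 1 signal unit) and $\gamma$ the load gain (default 0.05
per newton, so a 50 N load multiplies amplitude by 3.5). The scaling uses
the Gaussian identity $\mathbb{E}|X| = \sigma\sqrt{2/\pi}$. The default
profile gives every non-rest movement two dominant channels (factor 1.0),
two moderate (0.5) and four weak (0.15), with rest at 0.05 everywhere —
mimicking the channel-specific bursts seen under a real armband and
guaranteeing that classes are separable in expected-MAV space. Signal units
are arbitrary but consistent across the package.

What the generator deliberately does **not** model: motor-unit action
potentials, amplitude nonstationarity within a movement, electrode shift
between sessions, crosstalk structure, or fatigue. Passing tests on this
generator therefore demonstrate that the pipeline's machinery is correct
and recovers what it was built to recover — not that the same accuracy
would be observed on human recordings, where class overlap and drift are
the dominant difficulties.

## Time-domain features

Five features per channel and analysis window (40 for 8 channels): mean
absolute value (MAV), root mean square (RMS), variance (VAR), thresholded
zero crossings (ZC) and waveform length (WL). Three conventions are worth
stating because toolboxes differ:

* VAR uses the population normalization $1/N$.
* ZC and WL are normalized by $1/N$, making them rates rather than raw
  counts/sums, hence comparable across window lengths.
* The ZC threshold condition is $x_i x_{i+1} < 0$ **and**
  $|x_i - x_{i+1}| > x_{th}$; the absolute value makes the condition
  symmetric in the direction of the crossing.

Windows default to 200 ms with a 50 ms hop, standard myoelectric-control
practice. The ZC threshold $x_{th}$ defaults to 1% of each window's RMS,
which keeps the crossing rate invariant to signal gain; an absolute
threshold can be supplied instead.

## ReliefF selection

`relieff_weights()` implements canonical multiclass ReliefF: features are
min-max normalized to $[0,1]$, nearest neighbors are found under the
Manhattan distance, and for each evaluated instance the weight of feature
$f$ is updated by $-\mathrm{diff}$ to the $k$ nearest same-class hits and
$+P(C)/(1-P(\mathrm{own}))\cdot\mathrm{diff}$ to the $k$ nearest misses of
every other class $C$, averaged over $m$ evaluations. Defaults are $k=10$
and exhaustive iteration over all instances, which removes sampling noise
at the problem sizes this package targets; weights are then deterministic.
`select_top_per_channel()` keeps the two highest-weight features of each
channel (16 of 40), breaking boundary ties by the fixed order
MAV < RMS < VAR < ZC < WL so selection is reproducible.

## The classifier

A two-hidden-layer perceptron maps the 16 features to 7 classes. Hidden
width follows the sizing heuristic $M = \mathrm{round}(\sqrt{m+n}) + a$
(half-up rounding; $m=16$, $n=7$, $a=10$ give $M=15$). Hidden activations
are sigmoid by default — the classical BPNN choice; relu is available —
and the output layer is a softmax feeding the cross-entropy loss
$L = -\sum_i y_i \log \hat y_i$.

Training is full-batch gradient descent at learning rate 0.001 on the
*summed* (not averaged) cross-entropy over the training set, matching the
loss as written above. This choice matters numerically: on the summed loss
the gradient scales with the training-set size and 0.001 converges on the
separable synthetic set within a few thousand iterations, whereas on a
mean-reduced loss the same rate would need far more iterations. Weights
start Glorot-uniform ($\pm\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}$,
seeded); biases start at zero. Features are standardized with training-set
mean and standard deviation, stored in the model and applied internally at
prediction time — callers always pass raw features. The train/test split
is stratified 80/20. Training aborts with a diagnostic if the loss goes
non-finite. Exact probability ties at prediction go to the earlier label
in the model's label order.

## Decision smoothing and the command trigger

Raw per-window classifications are stabilized twice:

1. **Voting** (`smooth_stream()`): a sliding majority over the last 5
   outputs; each new result displaces the oldest and the vote is re-run.
   Ties keep the previous voted output when it is among the tied labels
   (minimizing command chatter), else the tied label appearing earliest in
   the window wins. The first 4 frames vote over the partial window, so
   output length equals input length — convenient for aligned evaluation.
2. **Trigger** (`trigger_step()`): a movement command is emitted exactly
   once when 5 consecutive identical voted labels arrive. The run must
   break before the same command can fire again (a refractory rule; the
   source behaviour for re-triggering was open, and one command per
   sustained posture is the safe reading for robot control), and `RELAX`
   never emits — rest is a state, not an instruction.

Under independent frame errors at accuracy $p$, a 5-window majority fails
only when at least 3 of 5 frames err *coherently*; the binomial bound
$\sum_{k \le 2}\binom{5}{k}(1-p)^k p^{5-k}$ (≈ 0.993 at $p = 0.907$) is
therefore conservative — scattered errors split across labels rarely
outvote the truth, and the measured smoothed accuracy sits above it. The
null model assumes the true movement is held across the window span, as in
an experiment where each movement is performed and held repeatedly; it
also assumes error independence, which flatters the filter relative to
real, temporally correlated classifier errors.

## Force estimation

**Static**: for each movement direction the relation between load and sEMG
amplitude is affine, $F = a\,\mathrm{MAV} + b$. `fit_static_model()`
averages MAV over repetitions within each load and regresses load
(newtons, response) on mean MAV by ordinary least squares — the direction
matches the model form, which has force on the left. The default protocol
emulated by the tests uses loads 5–50 N in 5 N steps, whole-recording MAVs,
three repetitions. `reference_static_models()` bundles a calibrated
coefficient set for the four directions (e.g. ulnar deviation
$F = 0.459\,\mathrm{MAV} + 4.863$) used as a fixture in tests and examples.

**Dynamic**: during movement with a held weight of mass $m$,

$$F_{dynamic}(t) = F_0 + m g + m r \ddot\beta(t),$$

with gravity $g = 9.81$ m/s² and lever arm $r = 0.07$ m (wrist rotation
center to the weight) by default, $\ddot\beta$ the flexion/extension
angular acceleration. A weight stated as a force $G$ converts as
$m = G/g$. The model reduces exactly to $F_0 + mg$ when $\ddot\beta \equiv 0$
and to $F_0$ when $m = 0$; both limits are asserted in the tests.
`generate_kinematics()` supplies minimum-jerk out-and-back angle traces
with analytic $\ddot\beta$; halving the movement time quadruples the peak
angular acceleration, which the fast mode exploits.

## Evaluation conventions

`accuracy_from_counts()` keeps accuracies as exact fractions; percent
values are display-rounded half-up to one decimal and never feed back into
computation. `compare_accuracy()` reports raw and voted per-frame accuracy
and their difference. `rmse()` is the usual root mean squared difference
between force traces.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the statistics stable while keeping a full run in the
minutes range on one core: 60 feature windows per movement (420 instances,
matching one 60-repetition acquisition set per class) for classification,
up to 5000 training iterations (the separable synthetic set converges well
before that; the 50,000-iteration default remains for harder data),
100,000-frame streams over 20 seeds for the voting null, and 100 seeds for
force-model parameter recovery. Zero probabilities are clamped to the
smallest positive double before logs; constant feature columns receive
ReliefF weight exactly 0 and unit scale in standardization; all generators
are deterministic given their seed, with per-recording seeds derived below
$2^{31}$.

## Known limitations

* The generator's amplitude-coded classes are easier than real sEMG;
  reported synthetic accuracies are construction-validity checks, upper
  bounds rather than forecasts.
* The voting analysis assumes iid frame errors and held movements;
  correlated error bursts longer than two frames defeat a 5-vote majority.
* The static force model is linear in MAV by design; it cannot capture
  amplitude saturation at high contraction levels.
* Force RMSE against measured human force depends on recorded subject
  data; the package reproduces the computation and validates it on
  synthetic traces with known ground truth instead.
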