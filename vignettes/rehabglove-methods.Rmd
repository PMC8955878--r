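---
title: "Methods: models, simulator and evaluation protocol in rehabglove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator and evaluation protocol in rehabglove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabglove)
```

`rehabglove` analyses recordings from a sensor glove worn on a paretic or
plegic hand during assisted self-rehabilitation: the patient moves the
affected hand with the healthy one through six prescribed joint-mobility
exercises while the glove streams accelerometer, gyroscope and flex-sensor
data. This vignette documents the models the package implements, the
choices made where the design was genuinely open, what the synthetic data
generator does and does not emulate, and the numerical details a user
re-deriving results will want.

## Sensor model

A sample carries eight channels plus a time stamp: acceleration `ax, ay,
az` (m/s²), angular velocity `gx, gy, gz` (rad/s), and two flex channels
`f1, f2` kept as raw 12-bit ADC counts (0–4095). Flex sensors are
deliberately not calibrated to bend angles — the resistive response is
nonlinear and drifts with wear, and the classifiers only need a
learnable monotone correlate of finger flexion. Sessions are whole-file
labelled: one exercise label and one anomaly flag per recording.

Session CSVs put the metadata in `# key: value` comment lines above the
column header; floats are written with six decimals and time as integer
milliseconds, so a write/read cycle reproduces a session exactly at that
precision and serialization is idempotent from the first rewrite on.
Invariant violations (ADC range, non-monotone time stamps, non-finite IMU
values) are rejected at read time with the offending row named — nothing
is silently repaired.

## Orientation: the complementary filter

Roll and pitch are estimated by the discrete complementary filter

$$\mathrm{roll}[n] = A\,(\mathrm{roll}[n-1] + g_x[n]\,\Delta T) +
(1-A)\,\mathrm{atan2}(a_y, a_z)$$

and analogously for pitch with $g_y$ and
$\mathrm{atan2}(-a_x, \sqrt{a_y^2+a_z^2})$. The gyroscope integrates well
over short horizons but drifts; the accelerometer tilt is drift-free but
noisy and corrupted by linear motion. The blend constant $A \in [0,1]$
trades these off; each update pulls the estimate toward the instantaneous
accelerometer tilt by a factor $(1-A)$, so under a static pose the error
decays geometrically as $A^n$ — a property the tests exploit in closed
form. Yaw is not produced: with the rotation axis parallel to gravity the
accelerometer cannot observe heading, and a magnetometer is out of scope.

Open choices made here:

* **A = 0.98 by default**, configurable. At 21 Hz this corresponds to a
  time constant of roughly 2.3 s, long enough to suppress
  motion-acceleration artefacts of slow assisted exercises (≈0.3–0.6 Hz)
  while correcting gyro drift well within a session.
* **Initialization**: the first sample of a session sets roll/pitch to its
  raw accelerometer tilt (no gyro term). Initializing at zero instead
  would inject a transient of up to the full base attitude; snapping to
  the first tilt reading removes it at the cost of first-sample noise.
* **Free fall** (`atan2(0,0)` undefined): the filter holds the previous
  angles and warns rather than erroring mid-stream.
* The square root in the pitch formula is the standard tilt construction;
  it keeps both atan2 arguments in acceleration units.

## Features, criteria and scaling

Each sample contributes the 10-vector
`[ax, ay, az, f1, f2, gx, gy, gz, roll, pitch]`; the last `Ns` of them,
oldest first, form the `Ns × 10` window matrix. Supported window lengths
are 10, 21 and 42 samples (≈0.5, 1 and 2 s at 21 Hz); 21 is the package
default.

Two scalar criteria summarize a window for the minimal classifier:
`Sacc`, the summed L1 norms of the acceleration vectors, and `Sflex`, the
summed absolute smoothed differences of the combined flex signal
`f1 + f2`. The smoothing kernel is rebuilt from its recipe rather than
hard-coded: a size-3 Gaussian with σ = 0.9 normalized to unit sum, full
convolution with the difference filter `[-1, 1]`, scaled by −2, each
coefficient rounded to one decimal. This yields
`[0.5, 0.4, -0.4, -0.5]`; unrounded, `[0.519, 0.443, -0.443, -0.519]`.
Rounding is half-away-from-zero (the rule that lands exactly on the
one-decimal reference coefficients; base R's `round` rounds half to even)
and can be disabled.
Numerical notes:

* The convolution in `Sflex` runs in **valid mode** within the window —
  only fully overlapping positions, `Ns - 3` of them — so no boundary
  values are invented and the streaming and batch computations agree.
* The kernel sums to zero, so constant flexion contributes nothing, and is
  antisymmetric, so replacing it by its reversed negation leaves `Sflex`
  unchanged (the criterion takes absolute values).

Min–max scaling `(x - xmin) / (xmax - xmin)` is fitted **per channel on
training data only**; scaled training data lies exactly in the unit box
while test data may leave it — that asymmetry is intentional and is what
makes the LOSO experiments honest (an unseen subject's flex baseline can
fall outside the training range). A channel with a degenerate training
range maps to 0.

## Classifiers

**Two-criteria tree.** CART with the Gini split criterion, depth capped at
3, fitted on `(Sacc, Sflex)` pairs of consecutive non-overlapping training
fragments. The cap is asserted structurally in the tests. The package uses
`rpart` with pruning disabled (`cp = 0`) so the depth cap is the only
complexity control. Fragments at a split threshold follow `rpart`'s
convention (values below the threshold go left); thresholds fall between
observed values, so training data never sits on one.

**Temporal convolutional networks.** One trunk, two heads. The trunk runs
two temporal convolutions (width 3) with ReLU, a max-pool of 2 between
them, global average pooling over time and a dense ReLU layer; the
exercise head is a 6-way softmax, the anomaly head a single sigmoid unit
(0 = anomaly, 1 = correct). The deployment target — on-device inference on
a small microcontroller — fixes the input (`Ns × 10`), the output shapes
and a compiled-model footprint of roughly 10 kB, but leaves the exact
layer parameters open; the package's default — 24 and 12 filters, dense
24, ≈2,100 weights — fits that footprint class with a hard guard of 5,000
parameters.
Because the trunk is shared, anomaly training can warm-start from trained
exercise weights (`init_from`), which the tests verify never hurts final
training loss in the median.

Training follows the file-sampling protocol: each batch element picks a
uniformly random training file and a uniformly random valid start index,
so windows never span file boundaries and long files are not oversampled
per window. Adam (learning rate 0.001) optimizes categorical or binary
cross-entropy. Epoch count, steps per epoch (default 12 × 60) and batch
size (64) are package defaults; the optimizer, learning rate and loss
functions are the fixed part of the training recipe. A single master seed fans out to
initialization and batch sampling, making loss traces bit-reproducible.
An explicit `forbid` argument lets callers assert that no test file
entered the training set; the experiment runner always does.

The anomaly score is binarized at 0.5 with ties counting as correct — the
generous direction, consistent with the scoring system's margin-of-error
philosophy.

## Scoring

Per-instant binary classifications accumulate into
`SCORE(n) = Σ anomalyclass(t)` from the first full window onward, and the
display shows `floor(numstars / (fs · p · Tmax) · SCORE(n))` stars. The
margin parameter `p = 0.8` means 80% correct interaction time already
earns the maximum; as printed the formula can exceed `numstars` for better
sessions, so the package clamps at `numstars` (five stars is described as
the perfect score, hence a ceiling). Stars are evaluated per sample and
displayed per second by the CLI; they are monotone non-decreasing within a
session because the score only accumulates.

## The synthetic data generator

The generator exists so that every pipeline stage has inputs with the
structure of a realistic multi-subject evaluation campaign for such a
device: 4 subjects, 292 sessions of
which 96 are anomalous, ≈1-minute sessions (durations uniform on 65–93 s,
mean 79 s) at 21 Hz, six exercises covered by every subject, anomalies
split between two modes. It synthesizes a ground-truth roll/pitch
trajectory directly and differentiates it for the gyroscope — guaranteeing
the complementary filter has a recoverable reference — rotates gravity
(9.81 m/s²) into the body frame plus a linear-motion term for the
accelerometer, and drives the flex channels with the exercise's
finger-flexion waveform quantized to integer ADC counts. Additive Gaussian
noise defaults: 0.2 m/s² (accelerometer), 0.02 rad/s (gyro), 8 counts
(flex).

Kinematic templates follow the exercise instructions: rolling is forearm
pronation/supination (dominant roll oscillation), wrist flexion–extension
a pitch oscillation with moderate finger excursion, wrist-and-fingers
extension slow with the largest flex excursion, basket hands-together
turning with statically bent fingers, hand up–down strong vertical
acceleration, hand kneading slow combined wrist/finger work. Movement
frequencies stay in the slow assisted band (0.3–0.6 Hz nominal). Two
aspects matter for realism of the *contrasts*:

* **Flex baselines are posture- and fit-dominated, not class-dominated**:
  baselines differ by ≤150 counts across exercises while per-subject
  glove-fit shifts have σ = 120 counts, so exercise identity in the flex
  channels comes from excursion and waveform, not from the resting level.
* **Base attitude varies widely per session** (σ = 0.35 rad): a hand laid
  on a table sits at many orientations, for resting and exercising alike.
  This overlaps the `Sacc` distributions of static anomalies and gentle
  exercises, which is precisely why the two-criteria tree cannot be
  perfect while the waveform-seeing networks can do better.

Anomalous variants emulate how patients fail to exercise, as described for
the original data collection (hands laid on the table, only small
movements): `rest` keeps a static attitude and flex baseline with sensor
noise only; `low_motion` scales all movement amplitudes to 10%. A richer
catalogue of anomalous behaviors would be straightforward to add behind
the same mode argument.

Subjects are profiles: multiplicative amplitude factors per channel group,
a tempo factor, glove-fit flex shift, random phases, and per-exercise
idiosyncrasies (a subject × exercise amplitude interaction). The
`variation` argument scales all these spreads. At the default 1 the
spread is large enough that leave-one-subject-out accuracy is measurably
below pooled five-fold accuracy; raising it degrades LOSO much faster
than pooled CV, since pooled folds can learn each subject's style while a
held-out subject's style is never seen. The exercises are pairwise
distinguishable by construction — for every pair of classes at least one
channel's population mean amplitude differs by ≥3 pooled standard
deviations — which is what makes ≥90% pooled synthetic accuracy
achievable at all.

What the generator does **not** emulate: non-stationary movement (fatigue,
pauses, tremor spectra), flex-sensor creep and step-response decay,
accelerometer bias, realistic spectral richness of human motion, or
spasticity. Passing tests on synthetic data therefore validate the
pipeline's mechanics and relative orderings, not clinical accuracy on real
patients.

## Evaluation protocol

Fragmenting: decision-tree training uses consecutive non-overlapping
fragments (`floor(L / Ns)` per file); network training samples random
windows; **testing always uses overlapping single-sample-shifted
fragments** (`L - Ns + 1` per file). Splits are at file level — five-fold
partitions the shuffled file list into near-equal test sets; LOSO holds
out one subject per fold (sorted id order) — so no window leaks across the
train/test boundary and the scaler is refitted per fold on training files
only.

The exercise task uses only non-anomalous files: every file carries an
exercise label, but a hand resting on a table carries no class signal, and
including such fragments would turn a six-way classification into a
mislabelled-data exercise. The anomaly task uses all files with *correct
exercising as the positive class* (the classification stream feeds a
score that counts correct instants, so "correct" is the detection target;
either convention is defensible, so it is stated explicitly here).

Metrics are precision, recall, f1 and accuracy; multiclass versions are
one-vs-rest averaged with support weights; fold aggregation is the sample
mean and (n−1) standard deviation; confusion matrices are row-normalized
by true-class cardinality, with zero-support rows emitted as zeros plus a
warning rather than NaN. Ablations (`noflex`, `nogyro`, `noaccel`,
`noangles`, `noimu`) physically remove columns and retrain from scratch
with the narrower input — an absent sensor is absent at training time too.
The tree only ever sees `Sacc` and `Sflex`, so ablations not touching
acceleration or flex channels reduce to the normal case for it; removing
one of its two inputs restricts the split search to the other, and
removing both is an error.

## Problem sizes used by the test suite

The end-to-end statistical tests run on the full default synthetic
dataset (292 sessions, 4 subjects) with window length 21: exercise
networks train 40 epochs × 60 steps, anomaly networks 25 × 60, with three
protocol seeds medianed for the headline comparisons and a single seed
for the ablation and variance sweeps. These sizes were chosen as the
smallest at which training demonstrably converges (pooled accuracy
plateaus) so that the qualitative orderings — pooled five-fold above
LOSO, CNN above tree on anomalies, `noimu` clearly degraded — are
properties of the models rather than of an undertrained optimizer.

## Known limitations

* The CNN layer geometry is one reasonable design within the
  microcontroller footprint, not the only possible one; it is fully
  configurable.
* The two anomaly modes are canonical stand-ins for a longer catalogue of
  observed incorrect behaviors.
* `Sflex`'s windowed (per-fragment) reading is adopted over a running
  stream interpretation; the two differ only at fragment boundaries.
* Scores are evaluated per sample but a deployed device might classify
  once per second; the CLI's `score` subcommand displays per-second lines
  over a per-sample accumulator.
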