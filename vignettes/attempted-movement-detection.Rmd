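---
title: "Detecting attempted movement from the EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting attempted movement from the EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainswitch)
```

## The problem

A patient under general anaesthesia who becomes aware cannot signal it: the
neuromuscular blocker abolishes movement but not cortical activity. A
natural reaction to awareness is trying to move, and attempted movement has
a well-characterized EEG signature over sensorimotor cortex:
event-related desynchronization (ERD), a power drop in the mu (8–12 Hz) and
beta (18–25 Hz) rhythms during the attempt, followed by event-related
synchronization (ERS), a transient rebound shortly after it ends. A *brain
switch* that detects this signature against an ongoing no-movement baseline
could alert the anaesthesiologist.

`brainswitch` implements that detection chain end to end as testable
components: an executable model of a cued two-phase experiment, a synthetic
EEG/EMG generator, BrainVision I/O, spatial filtering, Welch band-power
features, a regularized linear logistic classifier with cross-validated
evaluation and cross-condition transfer, confidence intervals, and a
sequential detector with false-alarm calibration.

## Session model

The experiment is cued: trials are 3 s auditory cues separated by 4 s of
silence, nine trials per sequence, with a rest between sequences. Phase 1
(before the block) has four conditions — actual, isometric, imagined and no
movement — with 81 trials each over three blocks; phase 2 (forearm blocked)
has attempted movement and no movement, 54 trials each in one block.
`build_session_plan()` realizes this as a timed event table; sequence order
within a block is a seeded permutation.

Totals force 3 sequences per condition per phase-1 block and 6 in the
phase-2 block. Two quantities the design leaves open are set as defaults
and exposed as arguments: the self-paced inter-sequence rest (10 s) and the
between-block rest (30 s). The practice block contributes no analyzed
trials and is not generated.

## What the synthetic data emulates — and what it does not

`generate_recording()` produces, per EEG channel, 1/f ("pink") Gaussian
background noise plus two narrowband rhythm sources (mu at 10 Hz, beta at
20 Hz, 2 Hz bandwidth) projected through a smooth spatial gain peaked at C3
— the right-hand task drives the contralateral cortex — with a weak (0.25)
mirror at C4. During each cue of condition $c$ the source amplitude is
scaled by $1-\mathrm{erd}(c)$ for 0–3 s and by $1+\mathrm{ers}(c)$ for
3.5–6 s, with raised-cosine ramps of 200 ms to avoid spectral splatter.
The ERS window is placed to coincide exactly with the rebound feature
window. The EMG pair carries band-limited (>20 Hz) bursts during cues whose
squared-envelope power is a configured percentage of the actual-movement
level, plus a small sensor noise floor.

Default effect sizes per condition (`default_condition_profiles()`):

| condition | erd_depth | ers_gain | emg_percent |
|-----------|-----------|----------|-------------|
| actual    | 0.50      | 0.40     | 100         |
| isometric | 0.50      | 0.40     | 1.2         |
| imagined  | 0.25      | 0.15     | 0.5         |
| attempted | 0.50      | 0.40     | 1.0         |
| none      | 0         | 0        | 0.5         |

No absolute ERD magnitudes are published for this paradigm, only
classification accuracies; the depths above are chosen once so that
executed/attempted movement is a strong but not saturated effect (a 0.5
amplitude drop is a factor 4 in band power, squarely in the range seen in
motor ERD studies), imagery is half as deep — it classifies worse, matching
the reported ordering — and rest is null. EMG percentages follow the
reported per-condition magnitudes (~1% of executed movement or less).
Amplitudes default to `rhythm_amp = noise_scale = 10` µV, i.e. a rhythm SNR
of 1 at the focal channel.

What the generator does **not** emulate: eye blinks and other artifacts,
line noise, electrode drift beyond what detrending removes, non-stationary
background, volume-conduction from a realistic head model, inter-subject
topography variation, or latency jitter of the response. Passing tests on
this data therefore show that the chain recovers the assumed signal
structure at realistic SNR and calibrates correctly under the null — not
that it would reach any particular accuracy on recorded human EEG.

## Preprocessing

**Detrending.** Each channel of each epoch ($[-1, 6)$ s around cue onset,
half-open, so the next cue at 7 s is never touched) has a least-squares
line removed, eliminating DC offset and slow drift. Fitted per epoch
because the epoch is the analysis unit; the operation is idempotent.

**Surface Laplacian.** The spherical-spline method interpolates the scalp
potential with the kernel
$g(x) = \frac{1}{4\pi}\sum_{n\ge1} \frac{2n+1}{n^m(n+1)^m} P_n(x)$
under a zero-sum constraint on the coefficients, and evaluates the surface
Laplacian through the companion kernel with order-$(m-1)$ weights. Because
the surface Laplacian of $P_n(\cos\theta)$ on the unit sphere is
$-n(n+1)P_n(\cos\theta)$, the operator carries a minus sign relative to the
interpolation series; this package keeps the true differential-operator
sign, so a focal positive potential has a negative Laplacian at its peak.
Constants: stiffness $m=4$, 50 Legendre terms, ridge $10^{-5}$ on the
interpolation matrix — the values of the original formulation and common
practice; all three are exposed via `spline_params()`. The whole operation
reduces to one montage-specific matrix multiply per time sample
(`laplacian_matrix()`), making linearity and reference-invariance exact by
construction. Electrode positions are an idealized spherical 10/20
construction (no digitized positions exist for this montage); intermediate
10%-system sites are normalized great-circle midpoints of their flanking
principal sites. CSP is deliberately absent: the study found no benefit
over the unsupervised Laplacian.

For the 9-channel analyses the Laplacian is computed on the full 30-channel
montage and features are then taken on the motor subset; whether the
original analysis re-derived the operator from 9 electrodes is not
documented, and the full-montage estimate is the better spatial derivative.

## Features

Welch PSD with 250 ms Hanning windows at 50% overlap gives a 4 Hz bin grid;
the 8–24 Hz band keeps exactly the bins {8, 12, 16, 20, 24} Hz. Separate
spectra over 0–3 s (ERD, during the cue) and 3.5–6 s (ERS, rebound) yield
`channels × 5 × 2` features — 90 for the motor set (C3, C4, Cz, F3, F4,
P3, P4, T7, T8), 300 for all 30 channels. Columns are ordered (channel,
frequency, window). Features are log10-transformed by default
(`log10_transform`): band power is approximately log-normal and the
transform conditions the classifier; the untransformed option is retained
since no published choice exists. The Welch normalization (PSD, window
power corrected, one-sided doubling) cancels in classification but is
pinned for tests against a single-window periodogram oracle.

Time-frequency maps (`tf_map()`) use the same windows sliding at 125 ms
across the whole epoch, trial-averaged, then divided per channel-frequency
by the mean over the full $-1$ to $6$ s epoch — the relative baseline: 1 is
average power, below 1 ERD, above 1 ERS. The map's sliding step is reused
from the feature windows; with 4 Hz resolution the lowest resolvable bin is
4 Hz, so maps cover 4–40 Hz.

**EMG.** The two EMG channels are re-referenced bipolarly, high-pass
filtered at 10 Hz (4th-order Butterworth, applied forward-backward for zero
phase; the original filter family is unstated), converted to instantaneous
amplitude via the FFT analytic signal, and averaged over 0.1–3.5 s per
trial. Per-condition percentages of the actual-movement level are computed
on squared envelope means ("power") by default, with a "magnitude" switch,
since the source material mixes both terms.

## Classifier

Binary, linear, quadratically regularized logistic regression: minimize
$\sum_i \log(1+e^{\eta_i}) - y_i\eta_i + \lambda\lVert w\rVert^2$ with the
bias unpenalized, features standardized internally (parameters stored and
reused at test time). Optimization is L-BFGS followed by Newton polishing
to a gradient max-norm below $10^{-6}$; a central-difference gradient
oracle verifies optimality in the tests. Regularization strength is
grid-searched over $\{10^{-3},10^{-2},10^{-1},1,10,100\}$ times the *total
data variance* — defined here, since no published definition exists, as the
sum over feature columns of their variance across training trials — scored
by stratified ten-fold cross-validated accuracy, ties broken toward the
stronger penalty (the simpler model).

Evaluation is stratified seeded ten-fold CV. By default the grid search
runs *nested* inside each training fold, which avoids selection bias; the
published description is ambiguous between nested and flat selection, so
`selection = "flat"` reproduces the simpler single-loop scheme. Transfer
(train on a phase-1 condition vs rest, test on attempted vs rest) fits once
on all training trials and evaluates once — different conditions make
cross-validation unnecessary — reusing the training standardization on the
test features.

## Statistics

Per-subject accuracies get exact Clopper–Pearson binomial intervals (beta
quantiles; `binom.test` is the oracle in the tests), with a
normal-approximation option. The published per-subject intervals are not
uniquely consistent with a single method and effective $n$, so they are not
reproduction targets; the group-level mean CIs — plain t intervals,
$\bar x \pm t_{0.975,n-1}\, s/\sqrt n$ — are exactly recomputable from the
printed per-subject accuracies and anchor the acceptance tests (upper
bounds above 100% are clipped only for display). A permutation harness
(`permutation_chance()`) verifies the 50% chance level empirically: with a
balanced two-class design, label shuffles must center the CV accuracy
distribution on 50%.

## The brain switch

Per-trial decision values (the classifier's linear scores, ordered in
time) are averaged over sliding windows of 8 consecutive trials — about one
minute at the 7 s pacing; a sign-vote combiner is available but the mean
preserves score magnitude and is the default. The alarm threshold is
calibrated on no-movement windows: for a 0% false-alarm target it sits just
above the null maximum ($\varepsilon = 10^{-9}$ of the score scale).
Calibration and evaluation use disjoint null windows, so the reported
false-alarm rate is honest — and noisy: stride-1 windows of 8 trials
overlap heavily, so the ~47 null windows of a phase-2 session contain only
a handful of effectively independent values, and the held-out false-alarm
rate of a zero-FA-calibrated threshold varies a lot across seeds while the
true-positive rate stays near ceiling. `characterize_detector()` traces
the full window/threshold trade-off. The published 0%/87.5% figures on human data
are a qualitative regime, not a numeric target; on strong-ERD synthetic
sessions the calibrated zero-false-alarm point holds a true-positive rate
well above 75%.

## Numerical choices and problem sizes

* Simulation rate: the hardware rate (2500 Hz) is the generator default,
  but all statistical checks and the worked analyses run at 200 Hz — every
  analyzed frequency is below 40 Hz, and 250 ms windows stay an integer 50
  samples, preserving the 4 Hz bin grid exactly while cutting memory and
  time by an order of magnitude. This is a deliberate design of the
  package's own test problem sizes.
* Chance-level verification uses 20 independently seeded null sessions
  (phase-2 design, zero effect everywhere); effect-recovery and detector
  checks use 10 strong-ERD sessions.
* Seeds: every stochastic routine takes an explicit seed;
  `derive_seed(seed, tag)` decorrelates stage streams deterministically.
  Identical configuration and seed reproduce every report byte for byte.
* Degenerate inputs: zero-variance features standardize to unit scale and
  contribute nothing; a zero total variance makes all grid candidates
  equal (the tie rule returns the last); separable data at tiny $\lambda$
  terminates on the iteration cap since the optimum is at infinity.
* The spline system is solved once per montage; `ridge = 0` is permitted
  but a singular interpolation matrix produces an instructive error.

## Known limitations

* Synthetic validation only: no recorded EEG ships with the package, so
  accuracy claims are about signal-structure recovery, not clinical
  performance.
* The cued design is built in; asynchronous (uncued) detection is out of
  scope, as in the source paradigm.
* Only the multiplexed IEEE float32 BrainVision dialect is supported,
  bit-exactly; other encodings are rejected rather than guessed. Marker
  files carry onset/duration/condition but not sequence/block indices —
  the TSV event sidecar is the lossless interface.
* Binary classification per condition-vs-rest only; discriminating between
  movement types is not the monitoring problem and is not implemented.
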