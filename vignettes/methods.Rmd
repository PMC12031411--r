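---
title: "Vibration-based activity classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibration-based activity classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagevibe)
```

## The measurement problem

A mouse moving inside its home cage applies small dynamic forces to the cage
structure — footfalls, grooming strokes, tugs at the drinking nozzle, rattling
of the metal feed rack. These forces excite structural vibrations that a
six-axis MEMS IMU can register, provided the signal rises above the sensor's
thermal noise. Mounting the IMU at the tip of a resonant cantilever beam,
tuned to the cage's mechanics, amplifies the vibration by resonance and makes
activity-induced vibrations measurable with a low-cost sensor, with no camera,
no line of sight, and no contact with the animal.

`cagevibe` implements the analysis chain around such a sensor: a simulator of
the beam-resonant signal structure, wavelet feature extraction, fusion of
resonance-coupled sensor axes, a decision-tree reference labeller for
video-tracking exports, a CNN-LSTM classifier, and the analytics used to
characterize both the signal and the classifier.

## The beam signal model (simulator)

The package cannot ship the original cage recordings, so every downstream
stage is exercised against a synthetic emulation of their structure. The
simulator is a *stylized* model, not a mechanical fit:

* **Oscillation modes.** Each force impulse rings a set of decaying
  sinusoids. The default beam has the two modes observed on the real device:
  94 Hz (vertical bending) and 906 Hz. Mode $j$ contributes
  $A\,g_{ij}\,e^{-2\pi f_j \zeta t}\sin(2\pi f_j t)$ to axis $i$, with
  damping ratio $\zeta = 0.02$ by default — the value is not dictated by the
  hardware, it is chosen so bursts decay visibly within half a second, as
  rapid decay is characteristic of the recorded bursts. It is configurable.
* **Cross-axis coupling.** A bending mode moves the IMU along one
  translation axis and around one rotation axis simultaneously, so pairs of
  channels carry the same modal signal at fixed relative amplitude and a
  quarter-period offset: the vertical mode couples $a_z$ and $\omega_x$ with
  relative amplitude 0.039688, the 906 Hz mode couples $a_y$ and $\omega_x$
  at 0.027865. In the simulator a donor axis *leads* the unit-gain axis by
  exactly $\lfloor \phi F_S / (2\pi f) \rfloor$ samples — an integer, so that
  the time-domain shift the fusion stage applies aligns the channels exactly.
  A real structure would show a fractional-sample offset; we accept this
  stylization because it makes the coupling-recovery invariant exact.
* **Sensor noise.** Per-axis white Gaussian noise, reflecting the thermal
  origin of MEMS noise. The accelerometer standard deviation is calibrated
  so an empty-cage rendering has acceleration-magnitude power
  $5.075\times10^{-6}\,g^2$; the $\omega_x$ noise is scaled by the 94 Hz
  coupling gain so that donor and primary channels have comparable SNR (the
  regime in which fusion is useful; grossly unequal SNRs are exercised
  separately in the tests).
* **Activity classes.** Classes differ in burst *timing* and *mode mix*:
  Resting has rare, tiny micro-movement bursts (~0.5 /s); Stationary
  Activity irregular strokes (~3 /s); Walking sparse step trains inside
  bouts separated by pauses (activity-specific vibrations are intermittent);
  Activity in Feeder frequent impulses that drive the high-frequency mode
  hard (metal rack contact); Drinking a regular burst train whose rate is
  drawn from 9–11 Hz per segment. Per-burst amplitudes carry log-normal
  jitter (log-sd 0.5, mean-one parameterization) to emulate the very large
  within-class power spread of real data.
* **Power calibration.** Each schedule entry's burst process is rescaled so
  the mean acceleration-magnitude power matches the per-class table in
  `class_power_targets()` (in $10^{-6} g^2$: Resting 8.129, Stationary 21.86,
  Walking 66.58, Feeder 91.97, Drinking 213.37 over a noise floor of 5.075).
  Note that the Resting target sits *above* the noise floor, which is why
  Resting segments contain micro-movement bursts rather than pure noise.
* **Paired label stream.** A 30 Hz frame stream emulates a video-tracking
  export: per-class raw-label mixes (grooming/sniffing/eating during
  stationary activity, etc.), centre-point velocities (< 0.05 cm/s when
  resting, ≥ 1.5 cm/s when walking, intermediate otherwise), feeder-area
  flags, and a small lost-tracking rate (0.5% invalid frames).
* **Study schedules.** `default_study_schedule()` draws multi-day bout
  sequences with a 12 h light phase starting at 07:00, a much higher
  non-resting share in the dark phase, long Resting bouts, short Walking
  bouts, and an elevated-activity acclimatization component decaying with a
  36 h time constant over roughly the first two days.

What passing tests on this data do **not** show: robustness to bedding
damping, multi-animal cages, non-stationary noise, drifting resonance
frequencies, or behaviours whose vibration signatures overlap more than
these stylized ones do. The simulator establishes that the pipeline's
machinery is correct and that its assumptions are internally consistent —
not that the classifier's accuracy transfers to any particular real cage.

## Feature extraction

Each analysis section (a non-overlapping window of 3–11 s; 9 s default) of
the four classification axes $a_x, a_y, a_z, \omega_y$ is decomposed with a
10-level multi-level discrete wavelet transform using the coif5 wavelet,
after a Tukey taper (ratio 0.1) over the whole section. Level $k$ covers
roughly $F_S/2^{k+1}$ to $F_S/2^k$ Hz; at 7 kHz the tenth level reaches down
to about 6.8 Hz and the remaining approximation (everything below) is
discarded from the feature set.

Two numerical choices deserve explanation:

* **Boundary handling is periodization**, not symmetric extension. With
  periodization the transform is exactly orthonormal: level-$k$ coefficient
  counts are exactly $\lceil N/2^k \rceil$ and coefficient energy equals
  windowed-signal energy to machine precision (the energy-conservation test
  asserts $10^{-6}$ relative on lengths divisible by $2^{10}$; for other
  lengths odd-length levels duplicate one boundary sample, which perturbs
  energy at the $10^{-3}$ level). The Tukey taper suppresses the wrap-around
  discontinuity that periodization would otherwise introduce.
* **Pooling is signed absolute-max.** All detail components are resampled
  to a common 200 Hz grid (enough to resolve the fastest ~10 Hz activity
  rate): blocks are pooled when the component is finer than 200 Hz and
  repeated when coarser. A plain max of zero-mean band-pass coefficients
  discards negative excursions, halving the visible burst amplitude, so the
  default pool keeps the signed value of largest magnitude (`pool = "max"`
  retains the plain convention).

Rows are stacked axis-major (10 levels × 4 axes = 40 rows of $200\,T$
columns) and normalized per row by the maximum absolute value — a per-matrix
scheme, so inference is self-contained with no global statistics to carry
around. Zero rows stay zero. A z-score alternative is available.

## Sensor fusion

For each calibrated oscillation mode, the detail component at the level
containing the mode frequency is replaced by an inverse-variance weighted
average of the coupled channels: the donor channel is shifted in the time
domain by $\lfloor \phi F_S/(2\pi f)\rfloor$ samples, decomposed separately,
rescaled to the primary axis's amplitude scale (dividing by its coupling
gain — the gain stores the donor's modal amplitude *relative to* the
unit-gain axis, and its noise variance scales accordingly), and combined
with weight

$$c = \frac{\sigma_1^{-2}}{\sigma_1^{-2} + \sigma_2^{-2}},\qquad
\sigma_\text{fused} = \sqrt{c^2\sigma_1^2 + (1-c)^2\sigma_2^2},$$

which for equal channel noise gives the
$\sigma_\text{fused}/\sigma_1 = 1/\sqrt{2} \approx 0.707$ amplitude
reduction. Channel noise variances are estimated per (axis, level) as sample
variances of an empty-cage (or resting) recording — the calibration data a
deployment would record anyway. The 906 Hz mode sits close to the 875 Hz
dyadic band edge of level 2; its level is pinned explicitly in
`default_fusion_arrays()` and a warning points users at the `level` override
whenever a mode frequency falls within 10% of a band edge. The fused
component replaces the classification (unit-gain) axis's row; the donor's
row is left untouched.

## Reference labelling

The 30 Hz frame stream is collapsed into one label per section by an ordered
threshold tree over relative durations computed on valid frames only
(sections under 50% valid are Uncertain):

1. Drinking at a 2/3 majority (nose-in-water detection is reliable);
2. Resting at an 80% majority *and* mean velocity below 0.05 cm/s (to keep
   very low-intensity activity out of Resting) — resting inside the feeder
   is still Resting, which is why this branch precedes the feeder branch;
3. Activity in Feeder when the centre point is inside the feed rack in at
   least 20% of frames;
4. Walking at an 80% majority (walking is brief and rarely pure);
5. Stationary Activity when grooming + sniffing + eating together reach
   2/3 — these three are grouped because video analysis cannot separate
   them reliably;
6. otherwise Uncertain, excluded from training and evaluation.

The branch order is a design choice: the published description fixes the
thresholds and the feeder-resting exception but not a total order, and the
order above is the one in which every stated constraint is satisfiable
simultaneously. Raw labels not referenced by any branch (Movement, Hopping,
Rearing) dilute all fractions and push mixed sections toward Uncertain,
which matches their role as transitional behaviours. Drinking precedes the
feeder branch because its detection is the most reliable of all classes.
The Uncertain fraction is monotone non-decreasing in the majority threshold
(tested by sweeping 0.5–0.9).

## The classifier

The network is a 1D convolution (filter size 100, 100 filters) over the
40-row feature matrix, a bidirectional LSTM (500 hidden units) returning the
full sequence, dropout 0.2, a second bidirectional LSTM (500 units)
returning its final states, and a dense softmax over the five classes.
Training uses Adam with initial learning rate 0.002, mini-batches of 50, a
global gradient-norm threshold of 1, at most 100 epochs with no early
stopping, and a stratified random 70/30 train/test split. Resting is
randomly undersampled to the Stationary Activity support before splitting,
so both appear with equal support in evaluation. A chronological split is
available for leakage-conscious analyses. The convolution layer is linear
by default — the printed architecture lists no activation between it and
the LSTM, whose gates supply the nonlinearity; a ReLU option exists.

The engine (forward pass, backpropagation through time, Adam, dropout) is
implemented in the package on top of BLAS matrix products, with batches laid
out `[channels, time, batch]` so each time step is one dense product over
the batch. Gradients are verified against numeric differentiation in the
test suite. Training is deterministic for a fixed seed under single-threaded
BLAS.

`reduced_network_spec()` (50 filters of width 20, stride 20, 100 hidden
units) preserves the layer structure at desk scale: the stride shortens the
LSTM sequence twentyfold, which is where the runtime lives. The synthetic
benchmark — 2,000 balanced 9 s sections, 70/30 split, 6 training epochs —
runs in roughly a quarter hour on one CPU with this spec and is the
configuration the end-to-end test uses. Epoch count and reduced-net shape
are package choices, not reproduction targets: with classes separable by
construction the loss plateaus within a handful of epochs.

## Analytics conventions

* **Energy and power.** The literal energy convention sums
  $(a_x^2+a_y^2+a_z^2)^2$ over a 0.2 s window; its units are $g^4$. The
  power default is the units-consistent mean of $a_x^2+a_y^2+a_z^2$ (in
  $g^2$, the scale of the per-class power table); the literal squared form
  stays available via `exponent = 2`. SNR is class power over empty-cage
  noise power, in ratio and dB (reports round dB to 2 decimals).
* **Metrics.** Confusion matrix, per-class precision/recall/F1, accuracy,
  macro (unweighted) and support-weighted F1. With equal supports the two
  averages coincide — a test identity. Metrics are cross-checked against an
  independent implementation (caret) in the suite.
* **Timelines.** Long-term monitoring groups section labels into 3 h bins
  and reports relative class occurrence among defined (valid, non-Uncertain)
  sections; bins with no defined sections stay empty rather than inheriting
  a neighbour's composition. `dominant_period()` extracts the strongest
  non-DC Fourier period of a fraction series — the circadian check asserts
  24 h on the default 7-day schedule.

## Degenerate inputs and tie-breaks

Empty sequences read and write as header-only files; all-zero sections
produce all-zero feature matrices (normalization leaves zero rows
unchanged); sections with no valid frames are Uncertain; argmax prediction
resolves probability ties by class order; an empty fusion-array list is the
identity on the decomposition; schedule entries must not overlap and
Uncertain never appears in a schedule.

## Known limitations

The simulator's class signatures are deliberately more separable than real
behaviour; held-out scores on synthetic data are an upper bound, not a
forecast. The DWT supports only coif5 (the wavelet actually used); the
fusion stage exercises channel pairs only, though the combiner formula
generalizes. IMU files are CSV only. The full-scale network trains in hours,
not minutes, on one CPU; the reduced spec exists precisely so the test suite
and desk-scale studies stay tractable.
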