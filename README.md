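# cagevibe

Non-contact activity classification for mice in their home cage, from the
vibrations the animal induces in the cage structure.

## The problem

Monitoring the behaviour of singly housed laboratory mice at scale is hard:
cameras need line of sight, fish-eye optics and per-cage compute; moving
animals to observation arenas biases the very behaviour being measured. A
six-axis IMU mounted on a resonant cantilever beam ("tuned beam") under the
cage floor senses the structural vibrations caused by footfalls, grooming,
feeding and drinking, amplified by the beam's resonance enough to clear the
sensor's thermal noise. From 3–11 s windows of this signal, five activity
classes can be recognized: **Resting**, **Stationary Activity** (grooming /
sniffing / eating), **Walking**, **Activity in Feeder**, and **Drinking**.

`cagevibe` implements the complete analysis chain for this sensing concept,
for researchers in animal-welfare monitoring and vibration-based activity
recognition:

* **Simulator** — tuned-beam IMU sessions with the beam's two oscillation
  modes (94 Hz and 906 Hz), cross-axis resonance coupling, per-class burst
  processes, power calibrated to the study-scale class table, plus a paired
  30 Hz behaviour-frame stream and multi-day circadian schedules
  (`generate_session()`, `default_study_schedule()`).
* **Feature extraction** — 10-level multi-level discrete wavelet transform
  (coif5, Tukey taper), max-pool resampling of every detail component to a
  common 200 Hz grid, per-row normalization: a 40 × 200·T feature matrix
  per analysis window (`build_feature_matrix()`).
* **Sensor fusion** — inverse-variance averaging of resonance-coupled axis
  pairs after time-domain phase alignment; equal-noise channels reduce the
  noise amplitude by 1/√2 ≈ 0.707 (`apply_fusion()`, `adaptive_combine()`).
* **Reference labelling** — a threshold decision tree collapsing 30 Hz
  video-tracking labels into one section label (2/3 majority; 80% plus a
  0.05 cm/s velocity ceiling for Resting; 20% feed-rack presence for
  Activity in Feeder; Uncertain otherwise) (`segment_stream()`).
* **Classifier** — CNN-LSTM (1D convolution → bidirectional LSTM →
  dropout → bidirectional LSTM → softmax) trained with Adam, gradient
  clipping and a stratified 70/30 split; the engine (BPTT and all) is
  implemented in the package and verified by numeric gradient checks
  (`train_classifier()`, `predict()`).
* **Analytics** — signal energy/power, per-class SNR, confusion-matrix
  metrics with macro/weighted F1, and 3 h monitoring timelines with a
  circadian period extractor (`signal_power()`, `snr()`,
  `classification_metrics()`, `aggregate_timeline()`).

## Worked example

```r
library(cagevibe)

cfg <- sim_config(seed = 7)
sched <- activity_schedule(
  label = c("Resting", "Drinking", "StationaryActivity"),
  start = c(0, 60, 90), end = c(60, 90, 150))
ses <- generate_session(cfg, sched)
ses$imu
#> <imu_sequence> 1050000 samples x 6 axes @ 7000 Hz (150.000 s, start 0.000 s)

noise <- signal_power(generate_session(cfg, NULL, duration = 60)$imu)
drink <- signal_power(imu_section(ses$imu, 60, 30))
sprintf("noise %.3e g^2, drinking %.3e g^2", noise, drink)
#> "noise 5.079e-06 g^2, drinking 2.136e-04 g^2"
snr(drink, noise)$db
#> 16.24
```

The noise floor lands on the calibrated 5.075×10⁻⁶ g² scale and drinking
reaches an SNR of ~42 (16.2 dB): drinking bursts are the strongest,
most regular vibration signature in the data. The paired frame stream
collapses into reference section labels:

```r
secs <- segment_stream(ses$frames, timeframe = 9, origin = 0)
table(secs$label)
#>          Drinking            Resting StationaryActivity          Uncertain
#>                 3                  6                  6                  1
```

(the window straddling the Resting→Drinking boundary is Uncertain and is
excluded from training and evaluation). One window becomes one classifier
input:

```r
fm <- build_feature_matrix(imu_section(ses$imu, 63, 9), timeframe = 9)
dim(fm)
#> 40 1800     # 4 axes x 10 wavelet levels, 9 s at 200 Hz
```

`synthetic_benchmark()` scales this up to a balanced 2,000-section dataset
on which the desk-scale network (`reduced_network_spec()`) reaches a
held-out macro F1 above 0.9 in a few training epochs; `run_pipeline()`
chains simulate → preprocess → label → train → predict → evaluate →
monitor with per-stage artifacts and content-hash resumption. A thin CLI
wrapper lives in `inst/cli/cagevibe.R`.

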