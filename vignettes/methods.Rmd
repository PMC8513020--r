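---
title: "Methods: four-state fatigue diagnosis from wearable gait sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-state fatigue diagnosis from wearable gait sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

Physical fatigue during walking alters gait timing, foot-impact mechanics,
torso motion and muscle activation. `gaitfatigue` implements a complete
desk-scale version of a wearable-sensor fatigue-diagnosis pipeline with four
ordinal fatigue states (`Low < Moderate < High < VeryHigh`), driven by
perceived exertion on the Borg CR10 scale banded as 0–2 / 3–5 / 6–8 / 9–10.

The stages, each an exported verb:

1. **Simulate** (`simulate_cohort()`): a cohort of walking bouts with known
   ground truth (heel-strike times, labels).
2. **Segment** (`segment_cohort()`): zero-phase low-pass filtering, heel-strike
   detection on the foot sagittal angular velocity, and partitioning into
   non-overlapping heel-strike-to-heel-strike windows.
3. **Features** (`extract_features()`): 43 per-cycle features — ten
   time/frequency statistics of the foot acceleration magnitude, nine of the
   foot angular-velocity magnitude, ten each for the L5-S1 accelerometer and
   gyroscope, and the RMS of four sEMG envelopes.
4. **Normalize** (`normalize_features()`): each feature divided by the
   participant's baseline reference — the mean of the first ten windows of
   bout 0, where the participant is not fatigued. This forces the mean of the
   first ten normalized baseline windows to 1 and removes between-subject
   scale.
5. **Label and model** (`assemble_dataset()`, `train_eval()`,
   `compare_models()`): six classifiers (RF, MLP, SVM, DT, KNN, multinomial
   LR) under a stratified 80/20 holdout or 10-fold CV, ranked by macro F1.
6. **Phase 2** (`rank_features()`, `reduce_and_eval()`, `sensor_ablation()`):
   impurity-based importance, top-k feature reduction, and retraining under
   sensor subsets (foot IMU only, L5-S1 only, both, all sensors).

`run_end_to_end()` chains all stages under one master seed and writes CSV/JSON
artifacts; `inst/scripts/run_pipeline.R` is a thin command-line wrapper.

## Heel-strike detection

On the foot sagittal angular velocity each gait cycle shows a toe-off
minimum, a prominent mid-swing maximum, and a heel-strike minimum. Counted
from the toe-off that opens the swing phase, **the heel strike is the second
minimum of its gait cycle** — the rule this detector implements. Strides are
anchored at the mid-swing maxima (local maxima above 50% of the signal
maximum, merged within a quarter stride); within each inter-maximum interval
the first minimum below a depth threshold is emitted, which is exactly that
second-of-the-cycle minimum. Taking instead the literal second minimum
between two maxima would emit toe-offs, because an inter-maximum interval
contains the completed stride's heel strike followed by the next stride's
toe-off.

The depth threshold is not fixed: 25 candidates spanning 10–60% of the
signal's negative range are scanned and the one minimizing the coefficient of
variation of inter-event intervals wins — treadmill cadence is nearly
constant, so the most regular event train is the right one. A refractory rule
(0.5 × running median interval) suppresses double detections. Both the
maximum anchors and the threshold grid are relative to the signal's own
range, so detection is invariant to uniform scaling (gain/unit changes).

Detection runs on the 6 Hz-filtered signal. The filter is a second-order
Butterworth applied forward–backward: zero phase, so event timing is not
lag-shifted, at the cost of squaring the magnitude response (a sinusoid at
the cutoff comes out at 0.5 amplitude, not 1/√2). Odd-reflection padding
brings the filter to steady state before the first real sample, so DC passes
exactly and edges carry no transient.

## Feature definitions

The windowed statistics are named but not defined in common usage, so the
package fixes them: `std`/`var` are population moments; `energy` is the mean
of squared samples (rate-independent); `entropy` is the Shannon entropy
(natural log) of a 16-equal-width-bin histogram of the window, 0 for constant
windows; `kurtosis` is Fisher excess kurtosis, 0 for zero-variance windows;
`maxfreq` is the frequency of the largest FFT magnitude excluding DC;
`stdfreq` is the standard deviation of the normalized non-DC power spectral
distribution; EMG `RMS` is the root mean square of the envelope on the EMG
clock over the same time interval. Tri-axial IMU channels are reduced to the
Euclidean magnitude before statistics, since the feature table carries one
value per statistic per sensor/modality, not per axis. The historical feature
names are preserved verbatim, including their spelling quirks
(`gait_curtosis_gyro`, `l2_Kurtosis_gyro`, `rms_tibilisAnterior`) and the
asymmetry that the foot gyroscope family has no `stdfreq` (index 9 is
`gait_stdfreq_acce`); heart rate is deliberately not a feature, as it tracks
exercise intensity rather than fatigue per se.

Feature extraction applies its own gentler low-pass (default 20 Hz) instead
of the 6 Hz detection filter: the heel-strike impact content on the foot
accelerometer lives around 15 Hz and is precisely the fatigue-sensitive
shock-attenuation signal, which a 6 Hz cutoff would erase. Both cutoffs are
configuration, not constants.

## The synthetic cohort

The generator emulates a treadmill protocol: 24 participants, five bouts each
(a non-fatigued baseline plus four progressively fatiguing rounds) of 120 s
walking; foot and L5-S1 tri-axial IMUs at 128 Hz, four sEMG envelopes
(gastrocnemius, tibialis anterior, rectus femoris, biceps femoris) at 512 Hz,
heart rate at 1 Hz. Borg readings follow a per-bout schedule (default 0, 2,
4, 7, 9 → Low, Low, Moderate, High, VeryHigh — a mild class imbalance with
Low largest, as in real cohorts).

Fatigue acts through per-round fractional effect ladders (round index
r = 0…4): cycle time × (1 + 0.05 r), heel-strike impact amplitude
× (1 + 0.05 r), torso-motion amplitude × (1 + 0.03 r), EMG envelope
× (1 − 0.10 r). The EMG sign encodes declining envelope amplitude with
muscular fatigue; the foot-acceleration sign is exposed as a parameter
because both directions are physiologically defensible (loss of shock
attenuation raises impact amplitude; slower walking lowers peak gait
acceleration) — the simulator takes no side.

The foot sagittal gyro is a stylized per-cycle template: a −cos fundamental
sway (120 deg/s), a mid-swing Gaussian maximum (+400 deg/s, σ = 0.10 cycle),
a toe-off Gaussian minimum (−200 deg/s, σ = 0.03) and a heel-strike Gaussian
dip (−120 deg/s, σ = 0.04 cycle) added in the time domain, centered exactly
on each ground-truth event. Three numerical choices matter: the sway has zero
slope at the cycle boundary, so it cannot shift the heel-strike minimum; the
dips are time-domain symmetric, so zero-phase filtering leaves their minima
in place; and the amplitudes are chosen so the cadence fundamental dominates
the spectrum even when 3% cycle-duration jitter splits the spectral line
across FFT bins. The foot accelerometer superimposes a decaying 15 Hz
oscillation at each heel strike (the impact transient) on a gravity-plus-gait
baseline. EMG is generated directly as a rectified envelope — tonic level
plus one activation burst per cycle per muscle — because the pipeline only
consumes envelope RMS; raw interference EMG is out of scope.

Variability model: per-cycle durations jitter with 3% CV; per-cycle,
per-muscle burst amplitudes jitter with 5% CV (cycle-to-cycle motor-unit
recruitment variation — without it a single EMG feature would be an
implausibly perfect classifier); all channels get additive Gaussian noise
(defaults: 0.3 m/s² accel, 5 deg/s gyro, 0.005 mV EMG, 1 bpm HR). Ground
truth includes a monotone lactate surrogate per bout (auxiliary label only)
and heart rate stays below the 90% HRmax stop rule (`safety_stop()`,
`tanaka_hrmax()` implement the rule itself).

What the generator does **not** emulate: musculoskeletal or metabolic
dynamics, treadmill-speed transients, electrode artifacts, missing data,
within-class heterogeneity of fatigue expression across participants, or
label noise in perceived exertion. Passing tests therefore demonstrate that
the pipeline's machinery is correct and recovers planted structure — not
that real-world classification will reach the same scores; real cohorts are
harder in exactly the ways listed.

## Models and metrics

The six classifier configurations are fixed: RF (100 trees), MLP (three tanh
hidden layers of 100 units, Adam at constant learning rate 1e-3, L2 1e-4,
max 1000 iterations, mini-batches of 200 with plateau early-stopping), SVM
(RBF kernel, cost 64, class-balanced weights), decision tree (entropy split,
max depth 12, min split 11, min leaf 4), 3-NN (Euclidean), and multinomial
logistic regression with inverse regularization strength 1e6 — effectively
unregularized maximum likelihood. RF, SVM, DT and KNN are fitted with
`randomForest`, `e1071`, `rpart` and `class`; the MLP is implemented in the
package because no installed R engine fits a multi-hidden-layer perceptron.
No other imbalance handling is applied beyond the SVM weights: the default
class distribution (≈40/20/20/20) is a slight imbalance, which is why macro
F1 — not accuracy — is the headline ranking metric.

Metrics come from the 4×4 confusion matrix (rows = truth): per-class
one-vs-rest precision and recall, F1 = 2PR/(P+R), accuracy = trace/total.
Both macro (mean of per-class values) and pooled/micro variants are computed
and labeled; for single-label multiclass prediction, pooled precision =
pooled recall = accuracy identically, which the tests assert as an identity.
Zero-denominator classes yield 0 with a warning rather than NaN.

Splitting is stratified by default (it stabilizes the two minority classes;
configurable off), row-wise by default with a participant-grouped option.
Row-wise splitting shares a participant's windows between train and test;
with per-participant baseline normalization this is a real leakage caveat for
generalization claims, which is why the grouped option exists. In k-fold
mode, headline metrics are fold means and the confusion matrix is the sum
over folds.

Feature reduction keeps the top-k features by normalized impurity importance
but **in their original column order**, so k = 43 reproduces the full design
matrix — and hence the full model at the same seed — exactly (tree ensembles
are column-order sensitive). Sensor ablation restricts columns by the fixed
sensor map (foot → indices 0–18, L5-S1 → 19–38, EMG → 39–42); EMG features
appear only in the `"all"` subset, since surface EMG is too invasive for
routine monitoring and the interesting question is what the IMUs alone
retain.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds through deterministic
sub-seed derivation, so every result in the test suite and the acceptance
script is exactly reproducible. The package's own verification uses: the full
default cohort (24 × 5 × 120 s, ≈ 12,000 gait cycles) for segmentation
recovery, the normalization law, classification and the reduction/ablation
grids; small cohorts (2–4 participants, 30–60 s bouts) for unit-level
properties; and 20 independent 4-participant null cohorts (all effect
ladders zeroed) for the no-signal check, where test accuracy is compared
against the class-prior baseline Σ p_c q_c (true priors × the classifier's
own prediction marginals) within its 95% binomial interval — the correct
expectation for a label-independent predictor.

## Known limitations

- The simulator's waveforms are stylized templates, not biomechanics; effect
  ladders are linear in the round index by construction.
- Borg-to-class banding assumes integer readings; half-point readings are not
  modeled.
- The lactate surrogate is ordinal plumbing, not a dose–response model.
- Row-wise splitting (the default) inflates scores relative to
  participant-grouped evaluation; use `partition_spec(group_by_participant =
  TRUE)` for generalization estimates.
- The reduction grid accepts per-row tree counts but performs no
  hyperparameter search; all model configurations are taken as fixed.
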