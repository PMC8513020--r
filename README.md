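# gaitfatigue

Four-state physical-fatigue diagnosis from wearable sensors during walking.

Clinicians supervising rehabilitation or exercise therapy need to know *how
fatigued* a patient is, not just *whether* they are fatigued: four ordinal
states (**Low < Moderate < High < VeryHigh**, banded from the Borg CR10
perceived-exertion scale as 0–2 / 3–5 / 6–8 / 9–10) let them time rest breaks
before fatigue becomes a fall or injury risk. `gaitfatigue` implements the
full analysis chain for diagnosing those states from wearable signals — foot
and lumbar (L5-S1) inertial units, surface-EMG envelopes of four leg muscles,
and heart rate — together with a synthetic-cohort generator that provides
ground truth for every stage.

The core of the method, per walking bout:

1. **Gait-cycle segmentation.** The foot sagittal angular velocity is
   low-pass filtered (order-2 Butterworth, zero-phase) and heel strikes are
   detected as the *second angular-velocity minimum of each stride* (toe-off
   is the first), with the depth threshold chosen by scanning candidates and
   keeping the one that minimizes the coefficient of variation of inter-event
   intervals. Each heel-strike-to-heel-strike interval is one non-overlapping
   analysis window.
2. **43 per-cycle features.** Ten time/frequency statistics (mean, std, max,
   var, median, energy, entropy, kurtosis, maxfreq, stdfreq) of the foot
   acceleration magnitude, nine of the foot angular velocity, ten each for
   the torso accelerometer/gyroscope, plus the RMS of the four sEMG
   envelopes.
3. **Baseline normalization.** Every feature `F_i` is divided by
   `F_reference`, the mean of its first ten windows of the non-fatigued
   baseline bout, removing between-subject scale:
   `F_i <- F_i / F_reference`.
4. **Classification.** Six classifiers — random forest (100 trees), a
   3×100-unit tanh MLP, RBF-SVM (C = 64, class-balanced), decision tree,
   3-NN and multinomial logistic regression — compared under a stratified
   80/20 split (or 10-fold CV) on accuracy, precision, recall and macro F1,
   with F1 the headline under class imbalance.
5. **Feature and sensor reduction.** Impurity-based importance ranking,
   top-k retraining (k = 25, 16, 13, 11, 8), and sensor-ablation grids
   quantifying what foot-only or IMU-only hardware retains.

## Worked example

```r
library(gaitfatigue)
library(dplyr)

cohort <- simulate_cohort(sim_config(n_participants = 4, bout_duration = 60,
                                     seed = 42))
cohort
#> <fatigue_cohort> 4 participants x 5 bouts (20 recordings of 60 s)
#>   class        n
#> 1 Low          8
#> 2 Moderate     4
#> 3 High         4
#> 4 VeryHigh     4

windows <- segment_cohort(cohort)
data <- cohort |>
  extract_features(windows) |>
  normalize_features() |>
  assemble_dataset(cohort$labels)
nrow(data)
#> [1] 979

cmp <- compare_models(data, partition = partition_spec(seed = 42))
select(cmp, algorithm, accuracy, precision, recall, f1, rank)
#>   algorithm accuracy precision recall    f1  rank
#> 1 RF           1         1      1     1         1
#> 2 LR           1         1      1     1         2
#> 3 ANN          0.995     0.997  0.994 0.995     3
#> 4 SVM          0.995     0.993  0.993 0.993     4
#> 5 DT           0.954     0.948  0.940 0.943     5
#> 6 KNN          0.628     0.569  0.566 0.567     6

rf <- cmp$fit[[match("RF", cmp$algorithm)]]
head(rank_features(rf), 5)
#>    rank feature             index importance cumulative
#> 1     1 rms_gastro             39     0.151       0.151
#> 2     2 rms_rectusFemoris      41     0.150       0.302
#> 3     3 rms_tibilisAnterior    40     0.144       0.446
#> 4     4 rms_bicepsFemoris      42     0.123       0.569
#> 5     5 l2_energy_gyro         34     0.0590      0.628
```

The 979 rows are the retained gait cycles of 20 bouts; each carries the 43
features and its bout's fatigue class. On this synthetic cohort the planted
effect ladder (cycle time +5%/round, EMG RMS −10%/round, foot-impact +5%/round)
makes the classes cleanly separable, so the forest reaches macro F1 = 1 on the
held-out 20% — the EMG RMS features dominating the importance ranking is
exactly the planted structure. `autoplot()` methods draw the cumulative
importance curve, confusion-matrix heatmaps and annotated signal traces;
`tidy()`/`glance()` return per-class and one-row metric tables.
`run_end_to_end(run_config(...))` chains everything and writes CSV/JSON
artifacts; `inst/scripts/run_pipeline.R` wraps it for the shell.

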