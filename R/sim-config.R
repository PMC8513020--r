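#' Simulation configuration for synthetic walking cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' study conditions the pipeline targets: 24 participants, five treadmill
#' bouts each (a non-fatigued baseline plus four progressively fatiguing
#' rounds) of 120 s walking, foot and L5-S1 IMUs at 128 Hz, four sEMG envelope
#' channels at 512 Hz and heart rate at 1 Hz.
#'
#' Fatigue acts through per-round fractional effect ladders: with round index
#' `r = 0..bouts-1`, cycle time is multiplied by `1 + effect_cycle_time * r`,
#' heel-strike impact amplitude by `1 + effect_foot_accel * r`, torso motion
#' amplitude by `1 + effect_torso * r` and every EMG envelope by
#' `1 + effect_emg_rms * r`. Fatigue-class labels come from `borg_schedule`
#' via [borg_to_class()].
#'
#' @param n_participants Number of participants (default 24).
#' @param bouts_per_participant Bouts per participant (default 5: baseline +
#'   four fatigue rounds).
#' @param bout_duration Walking-bout duration in seconds (default 120).
#' @param fs_imu,fs_emg,fs_hr Sampling rates in Hz for IMU, EMG envelope and
#'   heart-rate channels (defaults 128, 512, 1).
#' @param baseline_cycle_time Length-2 numeric: cohort mean and SD (seconds)
#'   of the participant-level baseline gait-cycle time; drawn values are kept
#'   in the physiological range 0.7-1.6 s.
#' @param effect_cycle_time Fractional cycle-time lengthening per fatigue
#'   round (default +0.05, i.e. +5% per round).
#' @param effect_foot_accel Fractional change of the heel-strike impact
#'   amplitude on the foot accelerometer per round (default +0.05). The sign
#'   is exposed deliberately: loss of shock attenuation raises impact
#'   amplitude, while slower walking lowers peak gait acceleration.
#' @param effect_emg_rms Fractional EMG envelope RMS drift per round
#'   (default -0.10).
#' @param effect_torso Fractional torso-motion amplitude drift per round
#'   (default +0.03).
#' @param cycle_cv Coefficient of variation of per-cycle duration jitter
#'   (default 0.03).
#' @param emg_cv Coefficient of variation of the per-cycle, per-muscle EMG
#'   burst amplitude (default 0.05), reflecting cycle-to-cycle variation in
#'   motor-unit recruitment.
#' @param noise_sd Named list of additive Gaussian noise SDs per modality:
#'   `accel` (m/s^2), `gyro` (deg/s), `emg` (mV), `hr` (bpm).
#' @param borg_schedule Integer Borg CR10 value per bout index (length
#'   `bouts_per_participant`); bout 0 must map to class "Low".
#' @param seed Master integer seed for the cohort.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_participants = 2, bout_duration = 30)
#' cfg$borg_schedule
#' @export
sim_config <- function(n_participants = 24,
                       bouts_per_participant = 5,
                       bout_duration = 120,
                       fs_imu = 128,
                       fs_emg = 512,
                       fs_hr = 1,
                       baseline_cycle_time = c(1.05, 0.08),
                       effect_cycle_time = 0.05,
                       effect_foot_accel = 0.05,
                       effect_emg_rms = -0.10,
                       effect_torso = 0.03,
                       cycle_cv = 0.03,
                       emg_cv = 0.05,
                       noise_sd = list(accel = 0.3, gyro = 5, emg = 0.005, hr = 1),
                       borg_schedule = c(0, 2, 4, 7, 9),
                       seed = 1L) {
  stopifnot(length(baseline_cycle_time) == 2)
  pos <- c(n_participants = n_participants,
           bouts_per_participant = bouts_per_participant,
           bout_duration = bout_duration,
           fs_imu = fs_imu, fs_emg = fs_emg, fs_hr = fs_hr,
           baseline_cycle_time_mean = baseline_cycle_time[1])
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("counts, durations and sampling rates must be strictly positive",
         call. = FALSE)
  }
  if (baseline_cycle_time[2] < 0 || cycle_cv < 0 || emg_cv < 0) {
    stop("spread parameters must be non-negative", call. = FALSE)
  }
  if (length(borg_schedule) != bouts_per_participant) {
    stop("`borg_schedule` must have one Borg value per bout", call. = FALSE)
  }
  cls <- borg_to_class(borg_schedule) # validates 0..10 integers
  if (as.character(cls[1]) != "Low") {
    stop("bout 0's Borg value must map to class \"Low\"", call. = FALSE)
  }
  for (m in c("accel", "gyro", "emg", "hr")) {
    if (is.null(noise_sd[[m]]) || noise_sd[[m]] < 0) {
      stop("`noise_sd` needs non-negative entries for accel, gyro, emg, hr",
           call. = FALSE)
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    bouts_per_participant = as.integer(bouts_per_participant),
    bout_duration = bout_duration,
    fs_imu = fs_imu, fs_emg = fs_emg, fs_hr = fs_hr,
    baseline_cycle_time = baseline_cycle_time,
    effect_cycle_time = effect_cycle_time,
    effect_foot_accel = effect_foot_accel,
    effect_emg_rms = effect_emg_rms,
    effect_torso = effect_torso,
    cycle_cv = cycle_cv,
    emg_cv = emg_cv,
    noise_sd = noise_sd,
    borg_schedule = as.integer(borg_schedule),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_participants, " participants x ",
      x$bouts_per_participant, " bouts of ", x$bout_duration, " s\n", sep = "")
  cat("  fs: IMU ", x$fs_imu, " Hz, EMG ", x$fs_emg, " Hz, HR ", x$fs_hr,
      " Hz\n", sep = "")
  cat("  effects/round: cycle ", x$effect_cycle_time, ", foot accel ",
      x$effect_foot_accel, ", EMG RMS ", x$effect_emg_rms, ", torso ",
      x$effect_torso, "\n", sep = "")
  cat("  Borg schedule: ", paste(x$borg_schedule, collapse = ", "),
      " -> ", paste(borg_to_class(x$borg_schedule), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

emg_muscles <- function() {
  c("gastro", "tibialisAnterior", "rectusFemoris", "bicepsFemoris")
}

#' Draw participant profiles for a cohort
#'
#' Samples per-participant descriptors (age, walking speed, baseline gait
#' cycle time, per-muscle baseline EMG amplitude) from cohort-level
#' distributions using participant-indexed sub-seeds, so profile `i` is
#' reproducible independently of cohort size.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per participant: `participant`, `age`,
#'   `walking_speed`, `baseline_cycle_time` and one `emg_base_*` column per
#'   muscle (gastrocnemius, tibialis anterior, rectus femoris, biceps
#'   femoris).
#' @export
participant_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(seq_len(config$n_participants), function(p) {
    with_seed(fan_seed(config$seed, 104729, p), {
      ct <- rnorm(1, config$baseline_cycle_time[1], config$baseline_cycle_time[2])
      ct <- min(max(ct, 0.7), 1.6)
      base <- setNames(runif(4, 0.08, 0.20), paste0("emg_base_", emg_muscles()))
      c(list(participant = p,
             age = round(rnorm(1, 21.75, 1.16), 1),
             walking_speed = round(runif(1, 0.9, 1.5), 2),
             baseline_cycle_time = ct),
        as.list(base))
    })
  })
  dplyr::bind_rows(rows)
}
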