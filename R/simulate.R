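# Synthetic walking-bout generator.
#
# The foot sagittal angular velocity is a stylized per-cycle template: a
# mid-swing Gaussian maximum, a toe-off Gaussian minimum, a heel-strike
# Gaussian minimum pinned to the cycle boundary, plus a -cos fundamental sway.
# The sway has zero slope at the boundary so it never shifts the heel-strike
# minimum; amplitudes/widths are chosen so the fundamental dominates the
# spectrum and the toe-off dip is the deepest minimum of each cycle (the heel
# strike is the cycle's second minimum, which is what the detector exploits).
GYRO_MS_AMP <- 400  # deg/s, mid-swing peak
GYRO_MS_PHASE <- 0.75
GYRO_MS_SIGMA <- 0.10  # cycle fraction
GYRO_TO_AMP <- 200  # toe-off dip depth
GYRO_TO_PHASE <- 0.60
GYRO_TO_SIGMA <- 0.03
GYRO_HS_AMP <- 120  # heel-strike dip depth, at the cycle boundary
GYRO_HS_SIGMA <- 0.04
GYRO_SWAY_AMP <- 120

IMPACT_AMP <- 4      # m/s^2 heel-strike shock amplitude at round 0
IMPACT_FREQ <- 15    # Hz decaying oscillation
IMPACT_TAU <- 0.04   # s decay constant

gyro_cycle_template <- function(u) {
  -GYRO_SWAY_AMP * cos(2 * pi * u) +
    GYRO_MS_AMP * exp(-(u - GYRO_MS_PHASE)^2 / (2 * GYRO_MS_SIGMA^2)) -
    GYRO_TO_AMP * exp(-(u - GYRO_TO_PHASE)^2 / (2 * GYRO_TO_SIGMA^2))
}

# heel-strike dips are added in the time domain, one symmetric Gaussian per
# event, so each local minimum sits exactly on the ground-truth time even
# when adjacent cycle durations differ
heel_strike_dips <- function(t, events, sigma_s) {
  y <- numeric(length(t))
  dt <- t[2] - t[1]
  span <- ceiling(4 * sigma_s / dt)
  for (e in events) {
    ic <- round(e / dt) + 1L
    i0 <- max(1L, ic - span); i1 <- min(length(t), ic + span)
    tt <- t[i0:i1] - e
    y[i0:i1] <- y[i0:i1] - GYRO_HS_AMP * exp(-tt^2 / (2 * sigma_s^2))
  }
  y
}

# map sample times to (segment, phase) given cycle boundaries
cycle_phase <- function(t, bounds) {
  seg <- findInterval(t, bounds, rightmost.closed = FALSE)
  seg[seg < 1] <- 1L
  seg[seg >= length(bounds)] <- length(bounds) - 1L
  u <- (t - bounds[seg]) / (bounds[seg + 1L] - bounds[seg])
  list(seg = seg, u = u)
}

impact_train <- function(t, events, amp) {
  y <- numeric(length(t))
  dt <- t[2] - t[1]
  span <- ceiling(0.25 / dt)
  for (e in events) {
    i0 <- max(1L, ceiling(e / dt) + 1L)
    i1 <- min(length(t), i0 + span)
    if (i0 > length(t)) next
    tt <- t[i0:i1] - e
    y[i0:i1] <- y[i0:i1] +
      amp * exp(-tt / IMPACT_TAU) * sin(2 * pi * IMPACT_FREQ * tt)
  }
  y
}

simulate_bout <- function(profile, config, bout, seed) {
  r <- bout - 1L # fatigue round index, 0-based
  Tb <- profile$baseline_cycle_time * (1 + config$effect_cycle_time * r)
  dur <- config$bout_duration
  if (dur < 3 * Tb) stop("bout too short", call. = FALSE)

  with_seed(seed, {
    ns <- config$noise_sd
    # ground-truth heel strikes: first at 0.3 cycles in, then jittered
    # cycles; the last event keeps a 4-sigma margin to the bout end so its
    # angular-velocity dip is fully observable
    end_margin <- 4 * GYRO_HS_SIGMA * Tb
    hs <- 0.3 * Tb
    repeat {
      z <- max(min(rnorm(1), 3), -3)
      Tk <- Tb * (1 + config$cycle_cv * z)
      if (hs[length(hs)] + Tk > dur - end_margin) break
      hs <- c(hs, hs[length(hs)] + Tk)
    }
    bounds <- c(hs[1] - Tb, hs, hs[length(hs)] + 2 * Tb)

    t_imu <- seq(0, by = 1 / config$fs_imu, length.out = floor(dur * config$fs_imu))
    ph <- cycle_phase(t_imu, bounds)
    u <- ph$u
    n <- length(t_imu)

    gyro_sag <- gyro_cycle_template(u) +
      heel_strike_dips(t_imu, hs, GYRO_HS_SIGMA * Tb)
    foot_gyro <- cbind(
      x = 30 * sin(2 * pi * u) + rnorm(n, 0, ns$gyro),
      y = 20 * sin(4 * pi * u) + rnorm(n, 0, ns$gyro),
      z = gyro_sag + rnorm(n, 0, ns$gyro)
    )

    imp <- impact_train(t_imu, hs, IMPACT_AMP * (1 + config$effect_foot_accel * r))
    foot_accel <- cbind(
      x = 0.5 * sin(2 * pi * u + 0.8) + imp + rnorm(n, 0, ns$accel),
      y = 0.4 * sin(4 * pi * u) + 0.5 * imp + rnorm(n, 0, ns$accel),
      z = 9.81 + 1.8 * sin(2 * pi * u) + 0.8 * imp + rnorm(n, 0, ns$accel)
    )

    s <- 1 + config$effect_torso * r
    torso_accel <- cbind(
      x = 0.8 * s * sin(4 * pi * u) + rnorm(n, 0, ns$accel),
      y = 0.6 * s * sin(2 * pi * u + 0.5) + rnorm(n, 0, ns$accel),
      z = 9.81 + 0.5 * s * sin(4 * pi * u + 0.3) + rnorm(n, 0, ns$accel)
    )
    torso_gyro <- cbind(
      x = 25 * s * sin(2 * pi * u + 1.0) + rnorm(n, 0, ns$gyro),
      y = 15 * s * sin(4 * pi * u + 0.7) + rnorm(n, 0, ns$gyro),
      z = 10 * s * sin(2 * pi * u) + rnorm(n, 0, ns$gyro)
    )

    # EMG envelopes: tonic level + one activation burst per cycle per muscle,
    # multiplicatively scaled by the per-round RMS drift
    t_emg <- seq(0, by = 1 / config$fs_emg, length.out = floor(dur * config$fs_emg))
    phe <- cycle_phase(t_emg, bounds)
    ue <- phe$u
    burst_phase <- c(gastro = 0.45, tibialisAnterior = 0.05,
                     rectusFemoris = 0.15, bicepsFemoris = 0.55)
    scale_emg <- 1 + config$effect_emg_rms * r
    n_seg <- length(bounds) - 1L
    # cycle-to-cycle motor-unit recruitment variability, per muscle
    amp_cycle <- matrix(pmax(1 + config$emg_cv * rnorm(n_seg * 4), 0.2),
                        n_seg, 4)
    emg <- sapply(seq_along(emg_muscles()), function(mi) {
      m <- emg_muscles()[mi]
      um <- burst_phase[[m]]
      base <- profile[[paste0("emg_base_", m)]]
      shape <- 0.35 +
        exp(-(ue - um)^2 / (2 * 0.09^2)) +
        exp(-(ue - um - 1)^2 / (2 * 0.09^2)) +
        exp(-(ue - um + 1)^2 / (2 * 0.09^2))
      pmax(base * scale_emg * amp_cycle[phe$seg, mi] * shape +
             rnorm(length(ue), 0, ns$emg), 1e-6)
    })
    colnames(emg) <- emg_muscles()

    n_hr <- max(1L, floor(dur * config$fs_hr))
    t_hr <- seq(0, by = 1 / config$fs_hr, length.out = n_hr)
    hr <- 88 + 8 * r + 5 * t_hr / dur + rnorm(n_hr, 0, ns$hr)

    rec <- structure(list(
      foot_accel = foot_accel, foot_gyro = foot_gyro,
      torso_accel = torso_accel, torso_gyro = torso_gyro,
      emg = emg, hr = hr,
      fs = list(imu = config$fs_imu, emg = config$fs_emg, hr = config$fs_hr),
      t0 = 0, duration = dur
    ), class = "bout_recording")
    list(recording = rec, heel_strikes = hs)
  })
}

#' @export
print.bout_recording <- function(x, ...) {
  cat("<bout_recording> ", x$duration, " s; IMU ", x$fs$imu, " Hz (",
      nrow(x$foot_accel), " samples x 4 triaxial channels), EMG ", x$fs$emg,
      " Hz (", nrow(x$emg), " samples x 4 muscles), HR ", x$fs$hr, " Hz\n",
      sep = "")
  invisible(x)
}

#' Simulate all bouts of one participant
#'
#' Generates one multi-channel recording per bout (foot/torso tri-axial IMU at
#' the IMU rate, four sEMG envelopes at the EMG rate, heart rate at 1 Hz)
#' together with ground truth: heel-strike times, Borg reading, fatigue class
#' and a monotone lactate surrogate per bout. Identical `(profile, config,
#' seed)` reproduce the output bit for bit.
#'
#' @param profile One row of [participant_profiles()].
#' @param config A [sim_config()].
#' @param seed Integer seed for this participant.
#' @return A list with `recordings` (list of `bout_recording`, one per bout)
#'   and `truth` (tibble: `bout`, `borg`, `class`, `lactate`, `n_cycles`,
#'   `mean_cycle_time`, list-column `heel_strikes` of event times in
#'   seconds).
#' @export
simulate_participant <- function(profile, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  bouts <- seq_len(config$bouts_per_participant)
  sims <- lapply(bouts, function(b) {
    simulate_bout(profile, config, b, fan_seed(seed, 7919, b))
  })
  lact_raw <- with_seed(fan_seed(seed, 15485863), {
    1.2 + 0.9 * (bouts - 1) + rnorm(length(bouts), 0, 0.08)
  })
  truth <- tibble::tibble(
    bout = bouts - 1L, # bout ids are 0-based: bout 0 is the baseline
    borg = config$borg_schedule,
    class = borg_to_class(config$borg_schedule),
    lactate = cummax(lact_raw),
    heel_strikes = lapply(sims, `[[`, "heel_strikes"),
    n_cycles = vapply(sims, function(s) length(s$heel_strikes) - 1L, integer(1)),
    mean_cycle_time = vapply(sims, function(s) mean(diff(s$heel_strikes)), double(1))
  )
  list(recordings = lapply(sims, `[[`, "recording"), truth = truth)
}

#' Simulate a full walking cohort
#'
#' Draws participant profiles and simulates every bout of every participant
#' with participant-indexed sub-seeds, so the cohort is reproducible and any
#' single participant can be regenerated independently.
#'
#' @param config A [sim_config()].
#' @return A `fatigue_cohort`: a list with `config`, `profiles` (tibble),
#'   `recordings` (tibble `participant`, `bout`, list-column `recording`),
#'   `truth` (per-bout ground truth incl. heel-strike times) and `labels`
#'   (tibble `participant`, `bout`, `borg`, `class`, `lactate`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 1, bout_duration = 20,
#'                                      seed = 7))
#' cohort$labels
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_participants < 1) stop("need at least one participant", call. = FALSE)
  profiles <- participant_profiles(config)
  per <- lapply(seq_len(config$n_participants), function(p) {
    sim <- simulate_participant(profiles[p, ], config, fan_seed(config$seed, p))
    list(
      recordings = tibble::tibble(
        participant = p,
        bout = sim$truth$bout,
        recording = sim$recordings
      ),
      truth = dplyr::mutate(sim$truth, participant = p, .before = 1)
    )
  })
  truth <- dplyr::bind_rows(lapply(per, `[[`, "truth"))
  structure(list(
    config = config,
    profiles = profiles,
    recordings = dplyr::bind_rows(lapply(per, `[[`, "recordings")),
    truth = truth,
    labels = dplyr::select(truth, "participant", "bout", "borg", "class", "lactate")
  ), class = "fatigue_cohort")
}

#' @export
print.fatigue_cohort <- function(x, ...) {
  cat("<fatigue_cohort> ", x$config$n_participants, " participants x ",
      x$config$bouts_per_participant, " bouts (", nrow(x$recordings),
      " recordings of ", x$config$bout_duration, " s)\n", sep = "")
  print(dplyr::count(x$labels, .data$class))
  invisible(x)
}

#' Write a cohort to CSV files plus a JSON manifest
#'
#' One CSV per (participant, bout, sensor) with a `time_s` column plus one
#' column per channel, and a `manifest.json` recording the configuration,
#' labels and file paths.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sensors <- c("foot_accel", "foot_gyro", "torso_accel", "torso_gyro", "emg", "hr")
  files <- list()
  for (i in seq_len(nrow(cohort$recordings))) {
    p <- cohort$recordings$participant[i]
    b <- cohort$recordings$bout[i]
    rec <- cohort$recordings$recording[[i]]
    for (s in sensors) {
      m <- rec[[s]]
      fs <- switch(s, emg = rec$fs$emg, hr = rec$fs$hr, rec$fs$imu)
      if (is.null(dim(m))) m <- cbind(value = m)
      df <- data.frame(time_s = (seq_len(nrow(m)) - 1) / fs, m)
      path <- file.path(dir, sprintf("p%02d_b%d_%s.csv", p, b, s))
      write.csv(df, path, row.names = FALSE)
      files[[sprintf("p%02d_b%d_%s", p, b, s)]] <- basename(path)
    }
  }
  manifest <- list(
    n_participants = cohort$config$n_participants,
    bouts_per_participant = cohort$config$bouts_per_participant,
    fs = list(imu = cohort$config$fs_imu, emg = cohort$config$fs_emg,
              hr = cohort$config$fs_hr),
    seed = cohort$config$seed,
    labels = cohort$labels,
    files = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
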