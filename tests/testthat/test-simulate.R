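test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_participants = 2, bout_duration = 20, seed = 9L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$heel_strikes, b$truth$heel_strikes)
  expect_identical(a$recordings$recording[[3]]$foot_gyro,
                   b$recordings$recording[[3]]$foot_gyro)
  expect_identical(a$recordings$recording[[7]]$emg,
                   b$recordings$recording[[7]]$emg)
})

test_that("with all effects and noise at zero, cycle time matches baseline", {
  cfg <- sim_config(n_participants = 1, bout_duration = 60,
                    effect_cycle_time = 0, effect_foot_accel = 0,
                    effect_emg_rms = 0, effect_torso = 0, cycle_cv = 0,
                    noise_sd = list(accel = 0, gyro = 0, emg = 0, hr = 0),
                    seed = 4L)
  cohort <- simulate_cohort(cfg)
  baseline <- cohort$profiles$baseline_cycle_time[1]
  for (i in seq_len(nrow(cohort$truth))) {
    expect_lt(abs(cohort$truth$mean_cycle_time[i] - baseline), 1 / cfg$fs_imu)
  }
})

test_that("a +5%/round cycle-time ladder lengthens bout 4 by ~20% over bout 0", {
  cfg <- sim_config(n_participants = 1, bout_duration = 120,
                    effect_cycle_time = 0.05, seed = 12L)
  cohort <- simulate_cohort(cfg)
  ct <- cohort$truth$mean_cycle_time
  expect_equal(ct[5] / ct[1], 1.20, tolerance = 0.02)
  # and the per-bout mean cycle time increases strictly with the round
  expect_true(all(diff(ct) > 0))
})

test_that("heel-strike counts are consistent with the realized cycle time", {
  cohort <- tiny_cohort()
  for (i in seq_len(nrow(cohort$truth))) {
    n_hs <- length(cohort$truth$heel_strikes[[i]])
    expected <- floor(cohort$config$bout_duration /
                        cohort$truth$mean_cycle_time[i])
    expect_lte(abs(n_hs - expected), 1)
  }
})

test_that("ground-truth heel strikes are strictly increasing with bounded jitter", {
  cohort <- tiny_cohort()
  for (hs in cohort$truth$heel_strikes) {
    d <- diff(hs)
    expect_true(all(d > 0))
    expect_true(all(abs(d - median(d)) <= 0.5 * median(d)))
  }
})

test_that("the foot gyro's dominant frequency is the cadence", {
  cohort <- tiny_cohort()
  fs <- cohort$config$fs_imu
  for (i in c(1, 5, 10)) {
    x <- cohort$recordings$recording[[i]]$foot_gyro[, "z"]
    n <- length(x)
    spec <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
    f_dom <- which.max(spec) * fs / n
    f_cad <- 1 / cohort$truth$mean_cycle_time[i]
    expect_lt(abs(f_dom - f_cad), fs / n + 1e-9)
  }
})

test_that("EMG envelope RMS scales with the per-round drift", {
  # cycle structure held fixed so the envelope shape is identical per bout
  # and the RMS ratio isolates the multiplicative drift
  cfg <- sim_config(n_participants = 1, bout_duration = 30,
                    effect_emg_rms = -0.10, effect_cycle_time = 0,
                    cycle_cv = 0, emg_cv = 0,
                    noise_sd = list(accel = 0, gyro = 0, emg = 0, hr = 0),
                    seed = 8L)
  cohort <- simulate_cohort(cfg)
  rms0 <- apply(cohort$recordings$recording[[1]]$emg, 2, function(x) sqrt(mean(x^2)))
  rms4 <- apply(cohort$recordings$recording[[5]]$emg, 2, function(x) sqrt(mean(x^2)))
  expect_equal(unname(rms4 / rms0), rep(0.6, 4), tolerance = 1e-6)
})

test_that("the lactate surrogate is non-decreasing across bouts", {
  cohort <- tiny_cohort()
  for (p in unique(cohort$labels$participant)) {
    la <- cohort$labels$lactate[cohort$labels$participant == p]
    expect_true(all(diff(la) >= 0))
  }
})

test_that("bouts shorter than three nominal cycles are rejected", {
  cfg <- sim_config(n_participants = 1, bout_duration = 2,
                    baseline_cycle_time = c(1.0, 0), seed = 1L)
  profile <- participant_profiles(cfg)[1, ]
  expect_error(simulate_participant(profile, cfg, 1L), "bout too short")
})

test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(n_participants = 0), "positive")
  expect_error(sim_config(fs_imu = -128), "positive")
  expect_error(sim_config(borg_schedule = c(0, 2, 4, 7)), "per bout")
  expect_error(sim_config(borg_schedule = c(5, 2, 4, 7, 9)), "Low")
  expect_error(sim_config(borg_schedule = c(0, 2, 4, 7, 12)))
})

test_that("cohort CSV export writes one file per sensor plus a manifest", {
  cohort <- simulate_cohort(sim_config(n_participants = 1,
                                       bouts_per_participant = 2,
                                       borg_schedule = c(0, 5),
                                       bout_duration = 10, seed = 2L))
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(cohort, dir)
  expect_true(file.exists(manifest_path))
  files <- list.files(dir, pattern = "\\.csv$")
  expect_length(files, 2 * 6) # 2 bouts x 6 sensor files
  one <- read.csv(file.path(dir, "p01_b0_foot_gyro.csv"))
  expect_named(one, c("time_s", "x", "y", "z"))
  manifest <- jsonlite::read_json(manifest_path)
  expect_equal(manifest$seed, 2L)
})
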