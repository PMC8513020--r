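test_that("window statistics follow the documented conventions", {
  x <- c(1, 2, 3, 4, 3, 2, 1, 2)
  s <- stat_features(c(1, 2, 3, 4, 1, 2, 3, 4), fs = 8)
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["var"]), 1.25) # population variance
  expect_equal(unname(s["median"]), 2.5)
  expect_equal(unname(s["energy"]), 7.5) # mean of squares
  expect_equal(unname(s["max"]), 4)

  const <- stat_features(rep(3, 32), fs = 128)
  expect_equal(unname(const[c("mean", "max", "median")]), c(3, 3, 3))
  expect_equal(unname(const[c("std", "var", "entropy", "kurtosis")]),
               c(0, 0, 0, 0))
  expect_equal(unname(const["energy"]), 9)

  expect_error(stat_features(1:7, 128), "window too short")
})

test_that("maxfreq finds a sinusoid's frequency within one FFT bin", {
  fs <- 128
  n <- 128
  t <- (0:(n - 1)) / fs
  s <- stat_features(sin(2 * pi * 2 * t), fs)
  expect_lt(abs(s[["maxfreq"]] - 2), fs / n + 1e-9)
})

test_that("every statistic matches a brute-force oracle on random windows", {
  set.seed(71)
  for (i in 1:25) {
    x <- rnorm(64, mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    got <- stat_features(x, fs = 128)
    want <- oracle_stats(x, fs = 128)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("statistics are scale-equivariant", {
  set.seed(5)
  x <- rnorm(64) + 2
  k <- 3.7
  a <- stat_features(x, 128)
  b <- stat_features(k * x, 128)
  for (lin in c("mean", "std", "max", "median")) {
    expect_equal(b[[lin]], k * a[[lin]], tolerance = 1e-12)
  }
  expect_equal(b[["var"]], k^2 * a[["var"]], tolerance = 1e-12)
  expect_equal(b[["energy"]], k^2 * a[["energy"]], tolerance = 1e-12)
  for (inv in c("entropy", "kurtosis", "maxfreq", "stdfreq")) {
    expect_equal(b[[inv]], a[[inv]], tolerance = 1e-9)
  }
})

test_that("a window yields exactly 43 named features", {
  expect_length(feature_names(), 43)
  expect_equal(anyDuplicated(feature_names()), 0)
  cohort <- tiny_cohort()
  rec <- cohort$recordings$recording[[1]]
  fv <- extract_window_features(rec, 1.0, 2.0)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  # spot-check the fixed naming quirks
  expect_true(all(c("gait_curtosis_gyro", "l2_Kurtosis_gyro",
                    "rms_tibilisAnterior", "gait_stdfreq_acce") %in%
                    names(fv)))
  # foot gyro family carries no stdfreq
  expect_false("gait_stdfreq_gyro" %in% names(fv))
})

test_that("EMG RMS features equal the envelope RMS on the EMG clock", {
  cohort <- tiny_cohort()
  rec <- cohort$recordings$recording[[1]]
  rec$emg[] <- 0.25 # constant envelope
  fv <- extract_window_features(rec, 1.0, 2.0)
  expect_equal(unname(fv[c("rms_gastro", "rms_tibilisAnterior",
                           "rms_rectusFemoris", "rms_bicepsFemoris")]),
               rep(0.25, 4))
  rec$emg <- NULL
  expect_error(extract_window_features(rec, 1.0, 2.0), "emg")
})

test_that("the baseline reference averages the first ten bout-0 windows", {
  feats <- cached("tiny_features", function() {
    cohort <- tiny_cohort()
    extract_features(cohort, segment_cohort(cohort))
  })
  ref <- compute_reference(feats)
  first10 <- feats |>
    dplyr::filter(participant == 1, bout == 0) |>
    dplyr::arrange(cycle) |>
    dplyr::slice(1:10)
  expect_equal(ref$gait_mean_acce[ref$participant == 1],
               mean(first10$gait_mean_acce))
  expect_equal(ref$rms_gastro[ref$participant == 1],
               mean(first10$rms_gastro))
  # fewer than ten baseline windows is an error
  expect_error(compute_reference(feats[feats$cycle <= 9, ]),
               "insufficient baseline")
  # a zero reference names the feature
  broken <- feats
  broken$rms_gastro[broken$bout == 0] <- 0
  expect_error(compute_reference(broken), "rms_gastro")
})

test_that("normalization forces unit baseline means and is idempotent", {
  feats <- cached("tiny_features", function() {
    cohort <- tiny_cohort()
    extract_features(cohort, segment_cohort(cohort))
  })
  norm <- normalize_features(feats)
  for (p in unique(norm$participant)) {
    base <- norm |>
      dplyr::filter(participant == p, bout == 0) |>
      dplyr::arrange(cycle) |>
      dplyr::slice(1:10)
    for (f in feature_names()) {
      expect_lt(abs(mean(base[[f]]) - 1), 1e-12)
    }
  }
  # renormalizing with a recomputed reference is the identity
  twice <- normalize_features(norm)
  for (f in feature_names()) {
    expect_lt(max(abs(twice[[f]] - norm[[f]])), 1e-12)
  }
  # simple division check
  one <- feats[1, ]
  ref <- compute_reference(feats)
  got <- normalize_features(one, ref)
  expect_equal(got$gait_max_acce,
               one$gait_max_acce / ref$gait_max_acce[ref$participant == 1])
})

test_that("normalization cancels per-participant channel scaling", {
  cohort <- simulate_cohort(sim_config(n_participants = 1, bout_duration = 30,
                                       seed = 55L))
  windows <- segment_cohort(cohort)
  scaled <- cohort
  for (i in seq_len(nrow(scaled$recordings))) {
    scaled$recordings$recording[[i]]$foot_accel <-
      2.5 * scaled$recordings$recording[[i]]$foot_accel
    scaled$recordings$recording[[i]]$emg <-
      0.4 * scaled$recordings$recording[[i]]$emg
  }
  a <- normalize_features(extract_features(cohort, windows))
  b <- normalize_features(extract_features(scaled, windows))
  # scale-dependent features are restored by the baseline division
  for (f in c("gait_mean_acce", "gait_max_acce", "gait_energy_acce",
              "rms_gastro", "rms_bicepsFemoris")) {
    expect_equal(b[[f]], a[[f]], tolerance = 1e-9)
  }
})

test_that("the assembled dataset is labeled, complete and order-invariant", {
  data <- tiny_dataset()
  cohort <- tiny_cohort()
  expect_true(all(c("participant", "bout", "cycle", "class") %in% names(data)))
  expect_false(anyNA(data[, feature_names()]))
  dist <- attr(data, "class_distribution")
  expect_equal(sum(dist$n), nrow(data))
  # shuffled input rows produce the identical sorted dataset
  feats <- cached("tiny_features", function() {
    extract_features(cohort, segment_cohort(cohort))
  })
  norm <- normalize_features(feats)
  shuffled <- norm[sample(nrow(norm)), ]
  expect_equal(assemble_dataset(norm, cohort$labels),
               assemble_dataset(shuffled, cohort$labels),
               ignore_attr = TRUE)
  # missing labels are an error
  expect_error(assemble_dataset(norm, cohort$labels[-1, ]), "label missing")
  # a baseline-only cohort is labeled entirely Low
  solo <- norm[norm$bout == 0, ]
  lab <- assemble_dataset(solo, cohort$labels)
  expect_true(all(lab$class == "Low"))
})
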