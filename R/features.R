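# Per-gait-cycle feature set: 10 time/frequency statistics of the foot
# acceleration magnitude, 9 of the foot angular-velocity magnitude, 10 each
# of the torso (L5-S1) acceleration and angular-velocity magnitudes, and the
# RMS of the four sEMG envelopes. Names (including their historical spelling
# quirks: "curtosis", "Kurtosis", "tibilisAnterior") are fixed verbatim so
# downstream tables are stable.

stat_order <- c("mean", "std", "max", "var", "median", "energy", "entropy",
                "kurtosis", "maxfreq", "stdfreq")

#' Names of the 43 per-cycle features, in column order
#'
#' Indices 0-9 foot acceleration, 10-18 foot angular velocity (no stdfreq),
#' 19-28 torso acceleration, 29-38 torso angular velocity, 39-42 EMG RMS.
#'
#' @return Character vector of length 43.
#' @export
feature_names <- function() {
  gait_acce <- paste0("gait_", stat_order, "_acce")
  gait_gyro <- paste0("gait_", c(head(stat_order, 7), "curtosis", "maxfreq"), "_gyro")
  l2_acce <- paste0("l2_", stat_order, "_acce")
  l2_gyro <- paste0("l2_", c(head(stat_order, 7), "Kurtosis", "maxfreq", "stdfreq"), "_gyro")
  emg <- c("rms_gastro", "rms_tibilisAnterior", "rms_rectusFemoris",
           "rms_bicepsFemoris")
  c(gait_acce, gait_gyro, l2_acce, l2_gyro, emg)
}

#' Sensor-to-feature index map
#'
#' Which of the 43 feature indices (0-based) each sensor contributes: the
#' foot IMU yields indices 0-18, the L5-S1 IMU 19-38, and the EMG units
#' 39-42.
#'
#' @return Named list of 0-based integer index vectors.
#' @export
sensor_feature_map <- function() {
  list(foot = 0:18, l5s1 = 19:38, emg = 39:42)
}

#' Time- and frequency-domain statistics of one window
#'
#' Computes the ten per-window statistics with these conventions: `std`/`var`
#' are population moments (divide by n); `energy` is the mean of squared
#' samples; `entropy` is the Shannon entropy (natural log) of a 16-bin
#' histogram of the window (0 for a constant window); `kurtosis` is Fisher
#' excess kurtosis, defined as 0 for zero-variance windows; `maxfreq` is the
#' frequency (Hz) of the largest FFT magnitude excluding the DC bin;
#' `stdfreq` is the standard deviation of the normalized (non-DC) power
#' spectral distribution. `maxfreq`/`stdfreq` are 0 when the window carries
#' no non-DC power.
#'
#' @param x Numeric window of at least 8 samples.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of the ten statistics.
#' @examples
#' stat_features(c(1, 2, 3, 4, 3, 2, 1, 2), fs = 8)
#' @export
stat_features <- function(x, fs) {
  n <- length(x)
  if (n < 8) stop("window too short", call. = FALSE)
  if (any(!is.finite(x))) stop("window contains non-finite values", call. = FALSE)
  m <- mean(x)
  v <- mean((x - m)^2) # population variance
  ent <- 0
  kur <- 0
  if (v > 0) {
    # 16 equal-width bins over [min, max]; top edge closed
    bin <- pmin(floor((x - min(x)) / (max(x) - min(x)) * 16), 15) + 1
    p <- tabulate(bin, nbins = 16) / n
    p <- p[p > 0]
    ent <- -sum(p * log(p))
    kur <- mean((x - m)^4) / v^2 - 3
  }
  spec <- Mod(fft(x))[seq_len(floor(n / 2)) + 1L] # non-DC half-spectrum
  freqs <- seq_len(floor(n / 2)) * fs / n
  pw <- spec^2
  if (sum(pw) > 0) {
    maxfreq <- freqs[which.max(spec)]
    pp <- pw / sum(pw)
    mu_f <- sum(pp * freqs)
    stdfreq <- sqrt(sum(pp * (freqs - mu_f)^2))
  } else {
    maxfreq <- 0
    stdfreq <- 0
  }
  c(mean = m, std = sqrt(v), max = max(x), var = v, median = median(x),
    energy = mean(x^2), entropy = ent, kurtosis = kur, maxfreq = maxfreq,
    stdfreq = stdfreq)
}

euclidean_magnitude <- function(m) sqrt(rowSums(m^2))

rms <- function(x) sqrt(mean(x^2))

#' Extract the 43 features of one gait-cycle window
#'
#' Tri-axial IMU channels are reduced to their Euclidean magnitude before the
#' statistics; EMG RMS is computed on the EMG clock over the same time
#' interval. Windows are half-open `[start_s, end_s)`.
#'
#' @param recording A `bout_recording`.
#' @param start_s,end_s Window bounds in seconds.
#' @return Named numeric vector of length 43 ([feature_names()]).
#' @export
extract_window_features <- function(recording, start_s, end_s) {
  stopifnot(inherits(recording, "bout_recording"))
  for (ch in c("foot_accel", "foot_gyro", "torso_accel", "torso_gyro", "emg")) {
    if (is.null(recording[[ch]])) {
      stop("missing channel: ", ch, call. = FALSE)
    }
  }
  ir <- window_index_range(start_s, end_s, recording$fs$imu)
  er <- window_index_range(start_s, end_s, recording$fs$emg)
  if (ir[2] > nrow(recording$foot_accel) || er[2] > nrow(recording$emg)) {
    stop("window extends beyond the recording", call. = FALSE)
  }
  idx <- ir[1]:ir[2]
  fs <- recording$fs$imu
  vals <- c(
    stat_features(euclidean_magnitude(recording$foot_accel[idx, , drop = FALSE]), fs),
    stat_features(euclidean_magnitude(recording$foot_gyro[idx, , drop = FALSE]), fs)[-10],
    stat_features(euclidean_magnitude(recording$torso_accel[idx, , drop = FALSE]), fs),
    stat_features(euclidean_magnitude(recording$torso_gyro[idx, , drop = FALSE]), fs),
    apply(recording$emg[er[1]:er[2], , drop = FALSE], 2, rms)
  )
  setNames(vals, feature_names())
}

#' Extract features for every retained window of a cohort
#'
#' Applies an optional noise-removal low-pass to the IMU channels of each
#' bout (default 20 Hz: well above gait kinematics but preserving the
#' ~15 Hz heel-strike impact content on the foot accelerometer), then
#' computes [extract_window_features()] for every `kept` window.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param windows A [segment_cohort()] result.
#' @param filter A [filter_spec()] for the IMU channels, or `NULL` for raw
#'   signals.
#' @return Tibble: `participant`, `bout`, `cycle`, then the 43 feature
#'   columns in [feature_names()] order.
#' @export
extract_features <- function(cohort, windows, filter = filter_spec(20)) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  keys <- dplyr::distinct(windows[windows$kept, ], .data$participant, .data$bout)
  rows <- purrr::pmap(keys, function(participant, bout) {
    rec <- cohort$recordings$recording[[
      which(cohort$recordings$participant == participant &
              cohort$recordings$bout == bout)]]
    if (!is.null(filter)) {
      for (ch in c("foot_accel", "foot_gyro", "torso_accel", "torso_gyro")) {
        rec[[ch]] <- lowpass_matrix(rec[[ch]], rec$fs$imu, filter)
      }
    }
    w <- windows[windows$kept & windows$participant == participant &
                   windows$bout == bout, ]
    feats <- t(vapply(seq_len(nrow(w)), function(i) {
      extract_window_features(rec, w$start_s[i], w$end_s[i])
    }, double(43)))
    dplyr::bind_cols(
      tibble::tibble(participant = participant, bout = bout, cycle = w$cycle),
      tibble::as_tibble(feats)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-participant baseline normalization reference
#'
#' The reference for each feature is the arithmetic mean of its first ten
#' windows (in cycle order) of bout 0, where the participant is not
#' fatigued. Every extracted feature is later divided by this reference.
#'
#' @param features A feature tibble from [extract_features()].
#' @param n_windows Number of leading baseline windows to average (default
#'   10).
#' @return Tibble: `participant` plus the 43 per-feature reference values.
#' @export
compute_reference <- function(features, n_windows = 10) {
  fn <- feature_names()
  stopifnot(all(fn %in% names(features)))
  refs <- features |>
    dplyr::filter(.data$bout == 0) |>
    dplyr::arrange(.data$participant, .data$cycle) |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < n_windows) stop("insufficient baseline", call. = FALSE)
      tibble::as_tibble(lapply(d[seq_len(n_windows), fn], mean))
    }) |>
    dplyr::ungroup()
  for (f in fn) {
    bad <- !is.finite(refs[[f]]) | refs[[f]] == 0
    if (any(bad)) {
      stop("degenerate reference for feature ", f, call. = FALSE)
    }
  }
  refs
}

#' Normalize features to each participant's non-fatigued baseline
#'
#' Divides every feature value by the participant's per-feature reference
#' (see [compute_reference()]), removing between-subject scale so that the
#' mean of the first ten normalized bout-0 windows is exactly 1 for every
#' feature.
#'
#' @param features A feature tibble from [extract_features()].
#' @param reference A [compute_reference()] tibble; computed from `features`
#'   when `NULL`.
#' @return The normalized feature tibble (same shape as `features`).
#' @export
normalize_features <- function(features, reference = NULL) {
  fn <- feature_names()
  if (is.null(reference)) reference <- compute_reference(features)
  missing_p <- setdiff(unique(features$participant), reference$participant)
  if (length(missing_p) > 0) {
    stop("participant(s) missing from reference: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  ord <- match(features$participant, reference$participant)
  out <- features
  for (f in fn) out[[f]] <- features[[f]] / reference[[f]][ord]
  out
}

#' Assemble the labeled per-cycle dataset
#'
#' Joins fatigue-class labels onto the feature rows, sorts rows by
#' participant/bout/cycle (so input order is irrelevant) and attaches a class
#' distribution report.
#'
#' @param features A (typically normalized) feature tibble.
#' @param labels A label tibble with `participant`, `bout`, `class` (and
#'   optionally `borg`, `lactate`), e.g. `cohort$labels`.
#' @return Tibble: `participant`, `bout`, `cycle`, `class`, auxiliary label
#'   columns, then the 43 features; class counts in
#'   `attr(, "class_distribution")`.
#' @export
assemble_dataset <- function(features, labels) {
  key_cols <- intersect(c("participant", "bout", "class", "borg", "lactate"),
                        names(labels))
  out <- dplyr::inner_join(features, labels[, key_cols],
                           by = c("participant", "bout"))
  if (nrow(out) < nrow(features)) {
    miss <- dplyr::anti_join(features, labels[, key_cols],
                             by = c("participant", "bout"))
    stop("label missing for participant/bout: ",
         paste(unique(paste(miss$participant, miss$bout, sep = "/")),
               collapse = ", "), call. = FALSE)
  }
  out <- out |>
    dplyr::relocate(dplyr::any_of(c("class", "borg", "lactate")),
                    .after = "cycle") |>
    dplyr::arrange(.data$participant, .data$bout, .data$cycle)
  attr(out, "class_distribution") <- dplyr::count(out, .data$class)
  out
}
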