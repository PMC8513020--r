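#' Detect heel strikes for every bout of a cohort
#'
#' Low-pass filters each bout's foot sagittal angular velocity (z axis of the
#' foot gyroscope) and runs [detect_heel_strikes()].
#'
#' @param cohort A [simulate_cohort()] result (or an identically shaped
#'   object with a `recordings` tibble of `bout_recording`s).
#' @param filter A [filter_spec()] applied before detection (default 6 Hz,
#'   order 2, zero phase).
#' @param ... Passed to [detect_heel_strikes()].
#' @return Tibble with `participant`, `bout`, `index`, `time_s`, one row per
#'   detected heel strike.
#' @export
detect_cohort_heel_strikes <- function(cohort, filter = filter_spec(), ...) {
  stopifnot(inherits(cohort, "fatigue_cohort"))
  rows <- purrr::pmap(cohort$recordings, function(participant, bout, recording) {
    sig <- lowpass_filter(recording$foot_gyro[, "z"], recording$fs$imu, filter)
    ev <- detect_heel_strikes(sig, recording$fs$imu, ...)
    tibble::tibble(participant = participant, bout = bout,
                   index = ev$index, time_s = ev$time_s)
  })
  dplyr::bind_rows(rows)
}

#' Segment a cohort into per-gait-cycle windows
#'
#' Runs heel-strike detection on every bout and partitions each bout into
#' non-overlapping heel-strike-to-heel-strike windows, discarding duration
#' outliers (beyond +/-50% of the bout median by default).
#'
#' @inheritParams detect_cohort_heel_strikes
#' @param outlier_frac Passed to [partition_cycles()].
#' @return Tibble with `participant`, `bout`, `cycle`, `start_s`, `end_s`,
#'   `duration`, `kept`. A per-bout discard log is attached as
#'   `attr(, "segmentation_log")`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 1, bout_duration = 20,
#'                                      seed = 3))
#' head(segment_cohort(cohort))
#' @export
segment_cohort <- function(cohort, filter = filter_spec(), outlier_frac = 0.5,
                           ...) {
  events <- detect_cohort_heel_strikes(cohort, filter = filter, ...)
  windows <- events |>
    dplyr::group_by(.data$participant, .data$bout) |>
    dplyr::group_modify(~ partition_cycles(.x, outlier_frac = outlier_frac)) |>
    dplyr::ungroup()
  log <- windows |>
    dplyr::group_by(.data$participant, .data$bout) |>
    dplyr::summarise(n_cycles = dplyr::n(), n_discarded = sum(!.data$kept),
                     .groups = "drop")
  attr(windows, "segmentation_log") <- log
  windows
}
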