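# Heel-strike detection from the foot sagittal angular velocity.
#
# Each stride shows a toe-off minimum, a mid-swing maximum and a heel-strike
# minimum; counted from the stride's toe-off, the heel strike is the second
# minimum. The detector anchors strides at the prominent mid-swing maxima and
# emits, within each inter-maximum interval (plus the leading and trailing
# segments), the first sub-threshold minimum - that minimum is exactly the
# second minimum of its gait cycle. The depth threshold is scanned over a
# fraction of the signal's negative range and chosen to minimize the
# coefficient of variation of inter-event intervals, i.e. the most regular
# cadence wins.

#' Detect heel strikes in a foot angular-velocity signal
#'
#' Finds heel-strike events as the per-stride second angular-velocity minimum
#' (see Details in the package vignette). Candidate depth thresholds spanning
#' `scan_range` of the signal's negative range are evaluated and the one
#' producing the most regular inter-event intervals (minimum CV) is kept; a
#' refractory rule (a fraction of the running median cycle length) suppresses
#' double detections within a stride. Detection is invariant to uniform
#' scaling of the signal because both the maximum anchors and the threshold
#' grid are relative to the signal's own range.
#'
#' @param x Filtered foot sagittal angular-velocity samples.
#' @param fs Sampling rate in Hz.
#' @param scan_range Fractions of the negative signal range to scan as depth
#'   thresholds (default `c(0.10, 0.60)`).
#' @param n_thresholds Number of thresholds in the scan (default 25).
#' @param refractory_frac Minimum event separation as a fraction of the
#'   running median cycle estimate (default 0.5).
#' @param max_frac Mid-swing maxima must exceed this fraction of the signal
#'   maximum (default 0.5).
#' @return A `gait_events` tibble with columns `index` (1-based sample index)
#'   and `time_s`; the chosen threshold, interval CV, and `fs` are attached
#'   as attributes.
#' @export
detect_heel_strikes <- function(x, fs, scan_range = c(0.10, 0.60),
                                n_thresholds = 25, refractory_frac = 0.5,
                                max_frac = 0.5) {
  if (length(x) < 3 || min(x) >= 0 || max(x) <= 0 || diff(range(x)) == 0) {
    stop("no gait detected", call. = FALSE)
  }
  maxima <- local_maxima(x)
  maxima <- maxima[x[maxima] > max_frac * max(x)]
  if (length(maxima) == 0) stop("no gait detected", call. = FALSE)
  # merge maxima closer than a quarter of the typical stride
  if (length(maxima) > 2) {
    typical <- median(diff(maxima))
    keep <- maxima[1]
    for (m in maxima[-1]) {
      if (m - keep[length(keep)] < 0.25 * typical) {
        if (x[m] > x[keep[length(keep)]]) keep[length(keep)] <- m
      } else keep <- c(keep, m)
    }
    maxima <- keep
  }
  minima <- local_minima(x)
  minima <- minima[x[minima] < 0]
  if (length(minima) == 0) stop("no gait detected", call. = FALSE)

  thresholds <- -seq(scan_range[1], scan_range[2],
                     length.out = n_thresholds) * abs(min(x))
  segments <- cbind(c(1L, maxima), c(maxima, length(x)))

  best <- NULL
  for (thr in thresholds) {
    cand <- minima[x[minima] < thr]
    if (length(cand) < 2) next
    ev <- integer(0)
    for (s in seq_len(nrow(segments))) {
      inseg <- cand[cand > segments[s, 1] & cand < segments[s, 2]]
      if (length(inseg) > 0) ev <- c(ev, inseg[1])
    }
    if (length(ev) < 3) next
    # refractory: drop events closer than refractory_frac x running median cycle
    kept <- ev[1]
    med <- median(diff(ev))
    for (e in ev[-1]) {
      gaps <- diff(kept)
      run_med <- if (length(gaps) >= 3) median(tail(gaps, 11)) else med
      if (e - kept[length(kept)] >= refractory_frac * run_med) kept <- c(kept, e)
    }
    if (length(kept) < 3) next
    cv <- sd(diff(kept)) / mean(diff(kept))
    if (is.null(best) || cv < best$cv) {
      best <- list(events = kept, threshold = thr, cv = cv)
    }
  }
  if (is.null(best)) stop("no gait detected", call. = FALSE)
  out <- tibble::tibble(index = best$events, time_s = (best$events - 1) / fs)
  attr(out, "threshold") <- best$threshold
  attr(out, "interval_cv") <- best$cv
  attr(out, "fs") <- fs
  class(out) <- c("gait_events", class(out))
  out
}

#' Partition a recording into gait-cycle windows
#'
#' Builds one non-overlapping, half-open window per consecutive heel-strike
#' pair. Cycles whose duration falls outside +/-50% of the bout's median
#' cycle are flagged as discarded (and excluded from feature extraction).
#'
#' @param events A [detect_heel_strikes()] result (needs `time_s`), or any
#'   tibble with heel-strike times in `time_s`.
#' @param outlier_frac Tolerated fractional deviation from the median cycle
#'   duration (default 0.5).
#' @return Tibble with `cycle` (1-based), `start_s`, `end_s` (half-open),
#'   `duration` and `kept` (logical; `FALSE` for duration outliers).
#' @export
partition_cycles <- function(events, outlier_frac = 0.5) {
  times <- events$time_s
  if (length(times) < 2) stop("insufficient events", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("heel-strike times must be strictly increasing", call. = FALSE)
  }
  dur <- diff(times)
  med <- median(dur)
  tibble::tibble(
    cycle = seq_along(dur),
    start_s = times[-length(times)],
    end_s = times[-1],
    duration = dur,
    kept = abs(dur - med) <= outlier_frac * med
  )
}

# half-open [start, end) sample index range of a time window on a channel
# clock; indices are 1-based into the sample array (sample i covers time
# (i-1)/fs).
window_index_range <- function(start_s, end_s, fs) {
  i0 <- floor(start_s * fs + 1e-9) + 1L
  i1 <- floor(end_s * fs - 1e-9) + 1L # last sample strictly before end_s
  c(i0, i1)
}
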