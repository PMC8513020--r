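#' Default physical plausibility bounds per modality
#'
#' Samples outside these bounds are treated as faulty sensor values during
#' cleaning and replaced by linear interpolation. Units: accel m/s^2, gyro
#' deg/s, EMG envelope mV, heart rate bpm.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
physical_bounds <- function() {
  list(accel = c(-160, 160), gyro = c(-2000, 2000),
       emg_envelope = c(0, 5), hr = c(25, 240))
}

#' Clean and synchronize multi-sensor channels
#'
#' Crops every channel to the common experimental window (the intersection of
#' all channel time spans, optionally further intersected with `window`),
#' re-expresses all channels on a shared time origin, and replaces samples
#' outside the per-modality physical bounds by linear interpolation from
#' their neighbours. The number of replaced samples per channel is returned
#' as a cleaning log.
#'
#' @param channels Tibble with columns `site`, `modality`, `axis`, `fs`, `t0`
#'   (channel start time in seconds) and a list-column `samples`.
#' @param window Optional length-2 numeric `c(start, end)` experimental
#'   window in seconds.
#' @param bounds Named list of physical bounds per modality, as
#'   [physical_bounds()].
#' @return A tibble shaped like `channels` with all `t0` equal to the common
#'   window start and samples cropped/cleaned; the per-channel replacement
#'   counts are in `attr(, "cleaning_log")`.
#' @export
clean_and_synchronize <- function(channels, window = NULL,
                                  bounds = physical_bounds()) {
  need <- c("site", "modality", "axis", "fs", "t0", "samples")
  if (!all(need %in% names(channels))) {
    stop("`channels` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  ends <- channels$t0 + vapply(channels$samples, length, integer(1)) / channels$fs
  w0 <- max(channels$t0)
  w1 <- min(ends)
  if (!is.null(window)) {
    w0 <- max(w0, window[1])
    w1 <- min(w1, window[2])
  }
  if (w1 <= w0) stop("no common window", call. = FALSE)

  log_rows <- list()
  out <- channels
  for (i in seq_len(nrow(channels))) {
    fs <- channels$fs[i]
    x <- channels$samples[[i]]
    # half-open [w0, w1) on this channel's clock
    i0 <- ceiling((w0 - channels$t0[i]) * fs - 1e-9) + 1L
    i1 <- floor((w1 - channels$t0[i]) * fs - 1e-9) + 1L
    x <- x[i0:min(i1, length(x))]
    b <- bounds[[channels$modality[i]]]
    n_bad <- 0L
    if (!is.null(b)) {
      bad <- !is.finite(x) | x < b[1] | x > b[2]
      n_bad <- sum(bad)
      if (n_bad == length(x)) stop("channel entirely out of bounds", call. = FALSE)
      if (n_bad > 0) {
        x[bad] <- NA_real_
        ok <- which(!is.na(x))
        x <- approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
      }
    }
    out$samples[[i]] <- x
    out$t0[i] <- w0
    log_rows[[i]] <- tibble::tibble(
      site = channels$site[i], modality = channels$modality[i],
      axis = channels$axis[i], n_replaced = n_bad
    )
  }
  attr(out, "cleaning_log") <- dplyr::bind_rows(log_rows)
  out
}
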