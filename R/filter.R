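#' Low-pass filter specification
#'
#' A second-order low-pass Butterworth, applied forward-backward (zero phase)
#' so gait-event timing is not lag-shifted. The cutoff is not dictated by the
#' sensing hardware; 6 Hz is the package default for IMU channels since
#' walking kinematics carry essentially all their energy below ~5 Hz.
#'
#' @param cutoff Cutoff frequency in Hz (default 6).
#' @param order Filter order (default 2).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(cutoff = 6, order = 2) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("invalid cutoff", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(list(cutoff = cutoff, order = as.integer(order), type = "low"),
            class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Filters a signal with an order-`spec$order` Butterworth low-pass applied
#' forward and backward ([signal::filtfilt()]), giving zero phase distortion
#' and a squared magnitude response (so a sinusoid at the cutoff is attenuated
#' to ~0.5 amplitude, not 1/sqrt(2)). DC is passed with unit gain.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 128
#' t <- seq(0, 2, by = 1 / fs)
#' lowpass_filter(sin(2 * pi * 1 * t), fs)[1:5]
#' @export
lowpass_filter <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2) stop("invalid cutoff", call. = FALSE)
  if (length(x) <= 3 * spec$order) {
    stop("signal too short for the filter order", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2), type = "low")
  # odd-reflection padding lets the forward-backward pass reach steady state
  # before the real samples, so DC passes exactly and edges are transient-free
  npad <- min(length(x) - 1L, ceiling(10 * fs / spec$cutoff))
  head_pad <- 2 * x[1] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(npad + 1L):(npad + length(x))]
}

lowpass_matrix <- function(m, fs, spec) {
  apply(m, 2, lowpass_filter, fs = fs, spec = spec)
}
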