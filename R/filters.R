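# Zero-phase filtering: 4th-order Butterworth sections run forward-backward
# (signal::filtfilt), plus an RBJ biquad notch at the mains frequency.

butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 4) {
  nyq <- fs / 2
  filt <- if (!is.null(low) && !is.null(high)) {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  } else if (!is.null(high)) {
    signal::butter(order, high / nyq, type = "low")
  } else {
    signal::butter(order, low / nyq, type = "high")
  }
  signal::filtfilt(filt, x)
}

# constrained-Q notch biquad (RBJ cookbook); run through filtfilt for zero
# phase, which also squares the magnitude response
notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_channels <- function(rec, fun) {
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, fun))
  out
}

#' Band-pass and notch pre-processing
#'
#' Applies a zero-phase (forward-backward) band-pass filter and a mains
#' notch, the standard conditioning step before spike detection and delay
#' estimation.
#'
#' @param rec a `tw_recording` with sampling rate >= 2 x the upper band edge.
#' @param band band edges in Hz (default `c(0.5, 120)`).
#' @param notch_hz mains frequency to notch out (default 50; `NULL` skips).
#' @param notch_q notch quality factor (default 30).
#' @return the filtered `tw_recording`.
#' @export
preprocess <- function(rec, band = c(0.5, 120), notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(rec, "tw_recording"))
  if (rec$sampling_rate < 2 * band[2])
    stop(sprintf("sampling rate %g Hz too low for %g Hz band edge",
                 rec$sampling_rate, band[2]))
  fs <- rec$sampling_rate
  nb <- if (!is.null(notch_hz)) notch_biquad(notch_hz, fs, notch_q)
  apply_channels(rec, function(x) {
    y <- butter_filtfilt(x, fs, low = band[1], high = band[2], order = 4)
    if (!is.null(notch_hz))
      y <- signal::filtfilt(signal::Arma(b = nb$b, a = nb$a), y)
    y
  })
}

#' Split a recording into slow and fast frequency components
#'
#' The spike (fast, beta-gamma) and wave (slow, delta-alpha) components of a
#' spike-wave discharge can travel differently, so delays are estimated per
#' band: below 13 Hz and 13-120 Hz.
#'
#' @param rec a pre-processed `tw_recording`.
#' @param split_hz boundary between the bands (default 13).
#' @param high_edge_hz upper edge of the fast band (default 120).
#' @return list with `low` and `high` `tw_recording`s.
#' @export
band_split <- function(rec, split_hz = 13, high_edge_hz = 120) {
  stopifnot(inherits(rec, "tw_recording"))
  fs <- rec$sampling_rate
  low <- apply_channels(rec, function(x)
    butter_filtfilt(x, fs, high = split_hz, order = 4))
  high <- apply_channels(rec, function(x)
    butter_filtfilt(x, fs, low = split_hz, high = high_edge_hz, order = 4))
  list(low = low, high = high)
}
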