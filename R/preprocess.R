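#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving a zero-phase response with no group delay.
#' Passband gain is approximately 1 and the stopband strongly attenuated.
#'
#' @param x Numeric vector, one channel of signal.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (default 4, standard EEG practice).
#' @return Filtered vector of the same length.
#' @examples
#' fs <- 128; t <- seq_len(2 * fs) / fs
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 50 * t)
#' y <- bandpass(x, 8, 14, fs)   # keeps the 10 Hz component
#' @export
bandpass <- function(x, low, high, fs, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop_input("band edges must satisfy 0 < low < high < fs/2 (got %g-%g Hz at fs=%g)",
               low, high, fs)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Decompose a signal into the four canonical bands
#'
#' Applies [bandpass()] per band (and per channel for matrix input).
#'
#' @param x Numeric vector (one channel) or channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param bands Band table as from [eeg_bands()].
#' @return A named list with one element per band, each the same shape as `x`.
#' @export
decompose_bands <- function(x, fs, bands = eeg_bands()) {
  validate_bands(bands)
  one <- function(v) lapply(seq_len(nrow(bands)), function(b)
    bandpass(v, bands$low[b], bands$high[b], fs))
  out <- if (is.matrix(x)) {
    lapply(seq_len(nrow(bands)), function(b) {
      t(apply(x, 1, function(v) bandpass(v, bands$low[b], bands$high[b], fs)))
    })
  } else one(x)
  names(out) <- bands$name
  out
}

#' Cut a signal into non-overlapping windows
#'
#' Contiguous, non-overlapping windows of `window_s` seconds; a trailing
#' remainder shorter than one window is dropped, so a 61 s record at a 2 s
#' window yields 30 windows. Concatenating the rows reconstructs the signal
#' prefix exactly.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 2).
#' @return A matrix with one window per row (`floor(length(x)/(window_s*fs))`
#'   rows, `window_s*fs` columns).
#' @export
segment_windows <- function(x, fs, window_s = 2) {
  wlen <- round(window_s * fs)
  if (wlen < 1) stop_input("window_s * fs must be >= 1")
  n <- length(x)
  if (n < wlen)
    stop_input("signal (%d samples) shorter than one window (%d samples)", n, wlen)
  nw <- n %/% wlen
  matrix(x[seq_len(nw * wlen)], nrow = nw, ncol = wlen, byrow = TRUE)
}
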