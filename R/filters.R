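#' Zero-phase band-pass plus mains-notch filtering
#'
#' Standard preprocessing for stimulus-locked electrophysiology: a 4th-order
#' Butterworth band-pass applied forward and backward (zero phase), followed
#' by zero-phase biquad notches (quality factor 30) at the mains frequency
#' and its integer harmonics up to the band's upper edge. EEG convention is
#' 0.5–70 Hz with a single 50 Hz notch; EMG convention is 10–500 Hz with
#' 50 Hz and harmonics. When the nominal upper edge reaches or exceeds the
#' Nyquist frequency (e.g. a 500 Hz edge at 500 Hz sampling) it is capped at
#' 0.95 of Nyquist and a warning of class `painforest_band_capped` is
#' signalled, which the pipeline logs and muffles.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz`.
#' @param notch_base_hz Mains frequency (Hz); `NULL` disables notching.
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 500; t <- seq(0, 2, by = 1 / fs)
#' mains <- sin(2 * pi * 50 * t)
#' filtered <- bandpass_notch_filter(mains, fs, 0.5, 70)
#' sqrt(mean(filtered^2))  # ~0: the notch removes 50 Hz
#' @export
bandpass_notch_filter <- function(x, fs, low_hz, high_hz,
                                  notch_base_hz = 50) {
  stopifnot(is.numeric(x), fs > 0)
  nyq <- fs / 2
  cap <- 0.95 * nyq
  if (high_hz >= nyq) {
    warning(warningCondition(sprintf(
      "upper band edge %g Hz >= Nyquist (%g Hz); capped at %g Hz",
      high_hz, nyq, cap), class = "painforest_band_capped"))
    high_hz <- cap
  }
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop(sprintf("invalid band after capping: [%g, %g] Hz at fs = %g",
                 low_hz, high_hz, fs))
  }
  bp <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bp, x)
  if (!is.null(notch_base_hz) && notch_base_hz > 0) {
    freqs <- seq(notch_base_hz, min(high_hz, cap), by = notch_base_hz)
    for (f0 in freqs) y <- notch_filtfilt(y, fs, f0, q = 30)
  }
  y
}

# Second-order IIR notch (RBJ biquad), applied zero-phase.
notch_filtfilt <- function(x, fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::filtfilt(filt = b / a[1], a = a / a[1], x)
}

# Modality-specific conventions used throughout the pipeline.
eeg_filter <- function(x, fs) bandpass_notch_filter(x, fs, 0.5, 70, 50)
emg_filter <- function(x, fs) bandpass_notch_filter(x, fs, 10, 500, 50)
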