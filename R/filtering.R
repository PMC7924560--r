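#' Butterworth low-pass filter specification
#'
#' The Butterworth low-pass has the maximally flat magnitude response
#' \deqn{|H(\omega)| = (1 + (\omega/\omega_0)^{2n})^{-1/2},}
#' whose squared gain at the cut-off frequency \eqn{\omega_0} is exactly 1/2
#' (the -3 dB point). Defaults (50 Hz cut-off, order 4) preserve the E/A/
#' ejection lobe morphology at fetal heart rates -- lobe content sits below
#' roughly 15 Hz -- while suppressing pixel-quantisation jitter.
#'
#' @param cutoff_hz cut-off frequency \eqn{\omega_0} in Hz (> 0).
#' @param order filter order n (positive integer); higher orders attenuate
#'   the stopband more steeply.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 50, order = 4L) {
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0) {
    stop("cutoff_hz must be a single positive number")
  }
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("order must be a positive integer")
  structure(list(cutoff_hz = as.numeric(cutoff_hz), order = order),
            class = "filter_spec")
}

#' Analytic Butterworth low-pass gain
#'
#' Magnitude response \eqn{(1 + (f/f_0)^{2n})^{-1/2}} of the analog
#' Butterworth low-pass. At `freq_hz = cutoff_hz` the squared gain is exactly
#' 1/2.
#'
#' @param freq_hz frequency (Hz), vectorised, non-negative.
#' @param spec a [filter_spec()].
#' @return dimensionless gain in (0, 1].
#' @examples
#' blpf_gain(0, filter_spec(25, 4))        # 1: DC passes unchanged
#' blpf_gain(25, filter_spec(25, 4))^2     # 1/2: the -3 dB point
#' @export
blpf_gain <- function(freq_hz, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (any(freq_hz < 0)) stop("frequency must be non-negative")
  (1 + (freq_hz / spec$cutoff_hz)^(2 * spec$order))^(-0.5)
}

#' Zero-phase Butterworth low-pass filtering of an envelope
#'
#' Applies the digital Butterworth low-pass (bilinear design at the signal's
#' sampling rate) forward and backward, so the effective amplitude response is
#' \eqn{|H(f)|^2} and the phase response is zero -- landmark times are not
#' shifted. Edge transients are controlled by odd-reflection padding, and the
#' signal mean is removed before filtering and restored afterwards, so a
#' constant signal passes through exactly.
#'
#' @param signal an [envelope_signal()].
#' @param spec a [filter_spec()]; the cut-off must lie below the Nyquist
#'   frequency `1000 / (2 * dt_ms)`.
#' @return the filtered [envelope_signal()], same length and timing.
#' @export
apply_lowpass <- function(signal, spec) {
  stopifnot(inherits(signal, "envelope_signal"), inherits(spec, "filter_spec"))
  fs <- 1000 / signal$dt_ms
  nyq <- fs / 2
  if (spec$cutoff_hz >= nyq) stop("cutoff above Nyquist")
  x <- signal$values
  if (length(x) < 3L * spec$order) stop("signal too short for this filter order")
  bf <- signal::butter(spec$order, spec$cutoff_hz / nyq, type = "low")
  mu <- mean(x)
  xc <- x - mu
  n <- length(xc)
  np <- min(n - 1L, 9L * (2L * spec$order + 1L))
  padded <- c(2 * xc[1L] - xc[(np + 1L):2L],
              xc,
              2 * xc[n] - xc[(n - 1L):(n - np)])
  y <- signal::filtfilt(bf, padded)
  out <- y[(np + 1L):(np + n)] + mu
  envelope_signal(out, signal$dt_ms, signal$origin_time_ms)
}
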