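# Preprocessing chains.
#
# Cardiac: select axis -> wavelet band reconstruction (10-40 Hz) ->
#   peak normalization -> 40-sample RMS envelope -> 1st-order Butterworth
#   band-pass 0.7-3 Hz. The envelope converts the heartbeat vibration packets
#   into a near-periodic wave whose fundamental is the heart rate.
# Respiratory: select axis -> 1st-order Butterworth band-pass 0.1-0.7 Hz.
# Reference channels are filtered at their native rates (250 / 25 Hz),
# never resampled; every stream is analyzed on its own frequency grid.

#' Single-channel signal container
#'
#' @param values numeric samples (finite).
#' @param fs sampling rate (Hz, > 0).
#' @param label provenance tag (sensor, axis, processing stage).
#' @return object of class `signal1d`.
#' @export
signal1d <- function(values, fs, label = "") {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("signal values must be finite numerics")
  if (fs <= 0) stop("fs must be > 0")
  structure(list(values = as.numeric(values), fs = fs, label = label),
            class = "signal1d")
}

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d> '%s': %d samples at %g Hz (%.1f s)\n",
              x$label, length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Select the analysis axis of a sensor
#'
#' Dimensionality reduction to one channel per sensor: by default the z axis
#' of the accelerometer (dorso-ventral) and the y axis of the gyroscope, the
#' axes that carry the strongest cardiorespiratory content on the chest.
#'
#' @param rec an `inertial_recording`.
#' @param sensor `"ACC"` or `"GYR"` (case-insensitive).
#' @param config a [default_config()]; fields `acc_axis` / `gyr_axis` choose
#'   the channel.
#' @return the selected channel, unchanged, as a [signal1d()].
#' @export
select_axis <- function(rec, sensor = c("ACC", "GYR"), config = default_config()) {
  sensor <- toupper(sensor[1])
  if (!sensor %in% c("ACC", "GYR")) stop("unknown sensor: ", sensor)
  axis <- if (sensor == "ACC") config$acc_axis else config$gyr_axis
  chan <- paste0(tolower(sensor), "_", axis)
  if (is.null(rec[[chan]])) stop("recording has no channel ", chan)
  signal1d(rec[[chan]], rec$fs, label = chan)
}

#' Wavelet band reconstruction
#'
#' Reconstructs the component of a signal inside a frequency band through an
#' analytic Morlet filter bank: the continuous wavelet transform is evaluated
#' at log-spaced scales whose center frequencies tile the band, and the
#' inverse transform (a weighted sum over those scales) is applied in one
#' pass as a zero-phase FFT-domain filter. The Gaussian passbands of the
#' Morlet atoms give a much sharper band edge than a 1st-order Butterworth,
#' which is the point of using it on the 10--40 Hz cardiac vibration band.
#'
#' @param sig a [signal1d()].
#' @param band `c(f_lo, f_hi)` in Hz, with `f_hi < fs/2`.
#' @param omega0 Morlet center frequency parameter (rad); 6 is the common
#'   default trading time against frequency localization.
#' @param n_voices scales per octave of the filter bank.
#' @return a [signal1d()], same length and rate.
#' @export
cwt_band_reconstruct <- function(sig, band, omega0 = 6, n_voices = 16) {
  stopifnot(inherits(sig, "signal1d"))
  n <- length(sig$values)
  if (n < 2 * sig$fs) stop("signal must be at least 2 s long")
  if (band[2] >= sig$fs / 2) stop("band upper edge must be below Nyquist")
  if (band[1] <= 0 || band[1] >= band[2]) stop("band must be ordered and positive")
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2 - 1), -1)) * sig$fs / n
  fc <- 2^(seq(log2(band[1]), log2(band[2]), by = 1 / n_voices))
  H <- numeric(n)
  for (fj in fc) {
    s <- omega0 / (2 * pi * fj)  # scale whose center frequency is fj
    H <- H + exp(-0.5 * (s * 2 * pi * abs(f) - omega0)^2)
  }
  H <- H / max(H)  # unit passband gain
  out <- Re(stats::fft(stats::fft(sig$values) * H, inverse = TRUE) / n)
  signal1d(out, sig$fs, label = paste0(sig$label, "|cwt", band[1], "-", band[2]))
}

#' Peak normalization
#'
#' Divides by the maximum absolute value so the signal spans \[-1, 1\]. The
#' downstream dominant-frequency estimate is scale-invariant, so this stage
#' only standardizes amplitudes across subjects and sensors.
#'
#' @param sig a [signal1d()]; must not be identically zero.
#' @return a [signal1d()] with `max(abs(values)) == 1`.
#' @export
normalize_peak <- function(sig) {
  stopifnot(inherits(sig, "signal1d"))
  m <- max(abs(sig$values))
  if (m == 0) stop("cannot normalize an all-zero signal")
  signal1d(sig$values / m, sig$fs, label = paste0(sig$label, "|norm"))
}

#' Sliding root-mean-square envelope
#'
#' Each output sample is the RMS of the input over a centered window of
#' `window` samples; at the edges the window shrinks to the available
#' samples, so the output has the input's length.
#'
#' @param sig a [signal1d()].
#' @param window window length in samples (>= 1, <= signal length).
#' @return a nonnegative [signal1d()].
#' @export
rms_envelope <- function(sig, window = 40L) {
  stopifnot(inherits(sig, "signal1d"))
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  n <- length(sig$values)
  if (window > n) stop("window exceeds signal length")
  cs <- cumsum(c(0, sig$values^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - (window - 1L) %/% 2L)
  hi <- pmin(n, i + window %/% 2L)
  out <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  signal1d(out, sig$fs, label = paste0(sig$label, "|rms", window))
}

# Digital Butterworth band-pass design at the signal's rate (bilinear
# transform with prewarped cutoffs, via signal::butter).
design_bandpass <- function(band, order, fs) {
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= fs / 2)
    stop("need 0 < f_lo < f_hi < fs/2 (fs = ", fs, " Hz)")
  signal::butter(order, band / (fs / 2), type = "pass")
}

#' Butterworth band-pass filter (zero phase)
#'
#' Designs a digital Butterworth band-pass of the given order at the
#' signal's own sampling rate and applies it forward-backward
#' ([signal::filtfilt()]), so the output is not phase-shifted and mechanical
#' and reference series stay aligned in time.
#'
#' @param sig a [signal1d()].
#' @param band `c(f_lo, f_hi)` in Hz with `0 < f_lo < f_hi < fs/2`.
#' @param order filter order of the single-pass prototype (1 in this
#'   pipeline).
#' @return a [signal1d()], same length.
#' @export
butter_bandpass <- function(sig, band, order = 1L) {
  stopifnot(inherits(sig, "signal1d"))
  filt <- design_bandpass(band, order, sig$fs)
  out <- as.numeric(signal::filtfilt(filt, sig$values))
  signal1d(out, sig$fs,
           label = paste0(sig$label, "|bp", band[1], "-", band[2]))
}

#' Single-pass Butterworth magnitude response
#'
#' Magnitude of the designed (single-pass) digital band-pass at the requested
#' frequencies; by the Butterworth definition it equals \eqn{1/\sqrt{2}} at
#' both cutoffs. The zero-phase application in [butter_bandpass()] squares
#' this response.
#'
#' @param band,order,fs as in [butter_bandpass()].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return numeric vector of magnitudes.
#' @export
filter_response <- function(band, order, fs, freqs) {
  filt <- design_bandpass(band, order, fs)
  z <- exp(-2i * pi * freqs / fs)
  num <- sapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)))
  den <- sapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)))
  Mod(num / den)
}

#' Cardiac preprocessing chain
#'
#' Axis selection, 10--40 Hz wavelet band reconstruction, peak normalization,
#' 40-sample RMS envelope and 0.7--3 Hz 1st-order Butterworth band-pass. The
#' result is a near-periodic wave at the heart rate, ready for spectral peak
#' extraction.
#'
#' @param rec an `inertial_recording`.
#' @param sensor `"ACC"` or `"GYR"`.
#' @param config a [default_config()].
#' @return a [signal1d()].
#' @export
cardiac_preprocess <- function(rec, sensor = "ACC", config = default_config()) {
  sig <- select_axis(rec, sensor, config)
  sig <- cwt_band_reconstruct(sig, config$cardiac_recon_band)
  sig <- normalize_peak(sig)
  sig <- rms_envelope(sig, config$envelope_window)
  butter_bandpass(sig, config$cardiac_band, config$filter_order)
}

#' Respiratory preprocessing chain
#'
#' Axis selection followed by a 0.1--0.7 Hz 1st-order Butterworth band-pass,
#' isolating the slow chest-wall oscillation while rejecting drift and
#' cardiac energy.
#'
#' @inheritParams cardiac_preprocess
#' @return a [signal1d()].
#' @export
respiratory_preprocess <- function(rec, sensor = "ACC", config = default_config()) {
  sig <- select_axis(rec, sensor, config)
  butter_bandpass(sig, config$resp_band, config$filter_order)
}

#' Reference preprocessing
#'
#' Band-passes the reference channel matching the mechanical chain: the ECG
#' at 0.7--3 Hz (emphasizing the R-wave periodicity) or the respiration
#' waveform at 0.1--0.7 Hz, each at its native sampling rate.
#'
#' @param ref a `reference_recording`.
#' @param target `"cardiac"` or `"respiratory"`.
#' @param config a [default_config()].
#' @return a [signal1d()].
#' @export
reference_preprocess <- function(ref, target = c("cardiac", "respiratory"),
                                 config = default_config()) {
  target <- match.arg(target)
  if (target == "cardiac") {
    sig <- signal1d(ref$ecg$ecg, ref$ecg$fs, label = "ref_ecg")
    butter_bandpass(sig, config$cardiac_band, config$filter_order)
  } else {
    sig <- signal1d(ref$resp$resp, ref$resp$fs, label = "ref_resp")
    butter_bandpass(sig, config$resp_band, config$filter_order)
  }
}
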