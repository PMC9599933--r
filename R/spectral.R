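# Sliding-window spectral rate extraction.
#
# Each preprocessed stream is cut into 1 s-step moving windows; each window
# gets a single-segment Welch PSD (window length = segment length, 0%
# overlap, Hamming taper, mean removal) zero-padded so the frequency grid
# spacing is the configured constant (0.166 mHz = 0.01 per-minute) for every
# window length and every sampling rate. The rate is 60 times the in-band
# dominant-peak frequency.

#' Segment a signal into sliding windows
#'
#' Windows of length `L` seconds starting every `step` seconds, fully
#' contained in the signal; for an integer-second signal of duration T and a
#' 1 s step there are T - L + 1 of them.
#'
#' @param sig a [signal1d()].
#' @param L window length (s).
#' @param step sliding step (s), 1 by default.
#' @return list of segments, each a list with `values`, `start` (s) and
#'   `center` (s).
#' @export
segment_windows <- function(sig, L, step = 1) {
  stopifnot(inherits(sig, "signal1d"), step > 0)
  T_s <- floor(length(sig$values) / sig$fs)
  if (L > T_s) stop("window length ", L, " s exceeds signal duration ", T_s, " s")
  starts <- seq(0, T_s - L, by = step)
  nwin <- round(L * sig$fs)
  lapply(starts, function(t0) {
    i0 <- round(t0 * sig$fs)
    list(values = sig$values[(i0 + 1):(i0 + nwin)],
         start = t0, center = t0 + L / 2)
  })
}

hamming_taper <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Single-segment Welch power spectral density at constant resolution
#'
#' Welch's method with the taper spanning the whole segment and 0% overlap
#' degenerates to a modified periodogram: the mean-removed, Hamming-tapered
#' segment is zero-padded to `NFFT = round(fs / resolution)` points so the
#' grid spacing `fs / NFFT` equals the configured resolution regardless of
#' the window length or sampling rate, making estimates comparable across
#' both. With `band` the PSD is evaluated only on the grid bins inside the
#' band (via a chirp-z transform, identical to the corresponding bins of the
#' full transform); otherwise the full one-sided grid is returned.
#'
#' @param x numeric segment (or a segment from [segment_windows()]).
#' @param fs sampling rate (Hz).
#' @param resolution target grid spacing (Hz); must not exceed
#'   `fs / length(x)` (zero padding only refines the grid).
#' @param band optional `c(f_lo, f_hi)` restriction (Hz).
#' @param detrend remove the segment mean before tapering (default TRUE;
#'   prevents DC leakage into the 0.1 Hz respiratory band edge).
#' @return object of class `psd_estimate`: `power` (one-sided density,
#'   units^2/Hz), `f_start` (Hz of the first bin), `resolution` (exact grid
#'   spacing `fs/NFFT`), `nfft`, `fs`, `total_power` (integrated two-sided
#'   power of the tapered segment, by Parseval).
#' @export
welch_psd <- function(x, fs, resolution = 0.01 / 60, band = NULL,
                      detrend = TRUE) {
  if (is.list(x)) x <- x$values
  n <- length(x)
  if (n == 0) stop("empty segment")
  nfft <- round(fs / resolution)
  if (nfft < n)
    stop("resolution coarser than the segment's natural fs/N; zero padding cannot coarsen the grid")
  res_exact <- fs / nfft
  w <- hamming_taper(n)
  y <- (if (detrend) x - mean(x) else x) * w
  scale <- 1 / (fs * sum(w^2))
  total <- sum(y^2) / sum(w^2)  # Parseval: integral of the two-sided PSD
  if (is.null(band)) {
    k0 <- 0L
    X <- stats::fft(c(y, numeric(nfft - n)))
    nkeep <- floor(nfft / 2) + 1L
    pw <- Mod(X[seq_len(nkeep)])^2 * scale
    pw[-1] <- pw[-1] * 2
    if (nfft %% 2 == 0) pw[nkeep] <- pw[nkeep] / 2
  } else {
    if (band[1] >= band[2] || band[2] > fs / 2) stop("invalid band for fs ", fs)
    k0 <- ceiling(band[1] / res_exact)
    k1 <- floor(band[2] / res_exact)
    if (k1 < k0) stop("band does not intersect the frequency grid")
    plan <- czt_plan(n, nfft, k0, k1)
    pw <- 2 * Mod(czt_exec(y, plan))^2 * scale
  }
  structure(list(power = pw, f_start = k0 * res_exact, resolution = res_exact,
                 nfft = nfft, fs = fs, total_power = total),
            class = "psd_estimate")
}

#' Frequency grid of a PSD estimate
#' @param psd a `psd_estimate`.
#' @return vector of bin frequencies (Hz).
#' @export
psd_frequencies <- function(psd) {
  psd$f_start + (seq_along(psd$power) - 1) * psd$resolution
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins from %.4f Hz, spacing %.6g Hz (fs %g Hz, NFFT %d)\n",
              length(x$power), x$f_start, x$resolution, x$fs, x$nfft))
  invisible(x)
}

#' Dominant in-band rate from a PSD
#'
#' 60 times the frequency of the largest PSD peak inside the band. Ties are
#' broken toward the lower frequency. If the band carries (numerically) no
#' power the estimate is flagged invalid and `NA` is returned; such gaps are
#' excluded pairwise from agreement statistics.
#'
#' @param psd a `psd_estimate`.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param power_floor invalidity threshold: the in-band maximum must exceed
#'   `power_floor * total_power` (and the total power must be nonzero).
#' @return rate in per-minute units (bpm / BrPM), or `NA_real_`.
#' @export
dominant_rate <- function(psd, band, power_floor = 1e-6) {
  f <- psd_frequencies(psd)
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel)) stop("band does not intersect the PSD grid")
  pw <- psd$power[sel]
  in_band <- sum(pw) * psd$resolution
  if (psd$total_power <= 0 || in_band < power_floor * psd$total_power)
    return(NA_real_)
  60 * f[sel[which.max(pw)]]
}

#' Extract a heart- or respiratory-rate time series
#'
#' Runs [segment_windows()], [welch_psd()] and [dominant_rate()] over every
#' sliding window of a preprocessed stream. Windows with no usable in-band
#' power (breath-holds in a clean reference respiration channel, numerically
#' silent segments) are kept in the series but flagged invalid. A window is
#' also invalidated when its total power collapses below `1e-6` times the
#' series' median window power, which catches windows lying entirely inside
#' an apnea where only filter ringing remains.
#'
#' @param sig a preprocessed [signal1d()].
#' @param band physiological search band `c(f_lo, f_hi)` (Hz); also the
#'   validity reference band.
#' @param L window length (s).
#' @param config a [default_config()] (step and PSD resolution).
#' @param source tag stored with the series (`"ACC"`, `"GYR"`,
#'   `"reference"`, ...); defaults to the signal label.
#' @return a `rate_series` data.frame with columns `window_center_s`, `rate`
#'   (per minute; `NA` where invalid) and `valid`; attributes
#'   `window_length`, `band`, `step`, `source`, `fs`.
#' @export
extract_rate_series <- function(sig, band, L, config = default_config(),
                                source = NULL) {
  stopifnot(inherits(sig, "signal1d"))
  step <- config$step
  resolution <- config$psd_resolution
  T_s <- floor(length(sig$values) / sig$fs)
  if (L > T_s) stop("window length ", L, " s exceeds signal duration ", T_s, " s")
  starts <- seq(0, T_s - L, by = step)
  n <- round(L * sig$fs)
  nfft <- round(sig$fs / resolution)
  res_exact <- sig$fs / nfft
  k0 <- ceiling(band[1] / res_exact)
  k1 <- floor(band[2] / res_exact)
  plan <- czt_plan(n, nfft, k0, k1)
  w <- hamming_taper(n)
  sw2 <- sum(w^2)
  scale <- 2 / (sig$fs * sw2)
  rate <- numeric(length(starts))
  tot <- numeric(length(starts))
  inb <- numeric(length(starts))
  for (j in seq_along(starts)) {
    i0 <- round(starts[j] * sig$fs)
    seg <- sig$values[(i0 + 1):(i0 + n)]
    y <- (seg - mean(seg)) * w
    pw <- Mod(czt_exec(y, plan))^2 * scale
    tot[j] <- sum(y^2) / sw2
    inb[j] <- sum(pw) * res_exact
    rate[j] <- if (tot[j] > 0) 60 * (k0 + which.max(pw) - 1) * res_exact else NA_real_
  }
  valid <- tot > 0 & inb >= 1e-6 * tot & tot >= 1e-6 * stats::median(tot)
  rate[!valid] <- NA_real_
  structure(
    data.frame(window_center_s = starts + L / 2, rate = rate, valid = valid),
    window_length = L, band = band, step = step,
    source = if (is.null(source)) sig$label else source, fs = sig$fs,
    class = c("rate_series", "data.frame"))
}

#' Write / read a rate series CSV
#'
#' Schema: metadata header lines (`# window_length_s=...`, `# band_hz=...`,
#' `# source=...`, `# step_s=...`) followed by
#' `window_center_s, rate, valid` rows.
#'
#' @param rs a `rate_series`.
#' @param path CSV file path.
#' @export
write_rate_series <- function(rs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# window_length_s=%g", attr(rs, "window_length")),
    sprintf("# band_hz=%g,%g", attr(rs, "band")[1], attr(rs, "band")[2]),
    sprintf("# source=%s", attr(rs, "source")),
    sprintf("# step_s=%g", attr(rs, "step"))), con)
  utils::write.csv(as.data.frame(rs), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_series
#' @export
read_rate_series <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  structure(df,
            window_length = as.numeric(meta$window_length_s),
            band = as.numeric(strsplit(meta$band_hz, ",")[[1]]),
            step = as.numeric(meta$step_s),
            source = meta$source,
            class = c("rate_series", "data.frame"))
}
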