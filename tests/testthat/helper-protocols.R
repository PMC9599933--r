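# Shared fixtures, all generated in code.

# Single-posture protocol with constant rates; noise off by default.
constant_protocol <- function(hr = 72, rr = 15, duration = 120, noise = 0,
                              apnea = list(), seed = 1, posture = "sitting") {
  noise_sd <- stats::setNames(noise, posture)
  subject_protocol(
    segments = data.frame(posture = posture, duration = duration),
    hr_trajectory = hr, rr_trajectory = rr,
    apnea_intervals = apnea, noise_sd = noise_sd, seed = seed)
}

# 5-subject sitting cohort with the default (sitting-level) noise and
# wandering HR (60-80 bpm) / RR (9-21 BrPM) trajectories, processed at all
# six window lengths. Computed once per test run and cached.
.cohort_env <- new.env(parent = emptyenv())

noisy_cohort_rates <- function() {
  if (!is.null(.cohort_env$rates)) return(.cohort_env$rates)
  cfg <- default_config()
  tbls <- lapply(1:5, function(i) {
    proto <- default_protocol(seed = 9000 + i, postures = "sitting")
    process_subject(synthesize_subject(proto), cfg,
                    windows = cfg$window_lengths,
                    subject_id = sprintf("s%d", i))
  })
  .cohort_env$rates <- do.call(rbind, c(tbls, make.row.names = FALSE))
  .cohort_env$rates
}

# Pooled-over-subject MAE rows from a rates table.
pooled_mae <- function(rates) {
  rep <- build_report(rates)
  rep[rep$subject == "all", c("vital", "sensor", "window_s", "mae", "n_pairs")]
}

# Independent periodogram dominant frequency (test oracle; no zero padding
# beyond the next power of two, plain rectangular periodogram).
oracle_dominant_freq <- function(x, fs, fmax = fs / 2, fmin = 0) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n * 32))
  pw <- Mod(fft(c(x - mean(x), numeric(nfft - n))))^2
  pw <- pw[1:(nfft / 2)]
  f <- (0:(nfft / 2 - 1)) * fs / nfft
  sel <- f >= fmin & f <= fmax
  f[sel][which.max(pw[sel])]
}

# Fraction of signal power inside [f1, f2], by direct periodogram integration.
band_power_fraction <- function(x, fs, f1, f2) {
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))^2
  pw <- pw[1:floor(n / 2)]
  f <- (0:(floor(n / 2) - 1)) * fs / n
  sum(pw[f >= f1 & f <= f2]) / sum(pw)
}
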