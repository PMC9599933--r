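test_that("axis selection returns the configured channel unchanged", {
  proto <- constant_protocol(duration = 5)
  rec <- synthesize_mechanical(proto)$recording
  expect_identical(select_axis(rec, "ACC")$values, rec$acc_z)
  expect_identical(select_axis(rec, "GYR")$values, rec$gyr_y)
  cfg <- default_config(acc_axis = "x")
  expect_identical(select_axis(rec, "ACC", cfg)$values, rec$acc_x)
  rec$acc_z <- rep(3, length(rec$time_s))
  expect_identical(select_axis(rec, "ACC")$values, rep(3, length(rec$time_s)))
  expect_error(select_axis(rec, "MAG"), "unknown sensor")
  expect_error(select_axis(rec, "ACC", default_config(acc_axis = "w")), "acc_w")
})

test_that("wavelet band reconstruction keeps in-band and rejects out-of-band tones", {
  fs <- 120
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  tone_in <- signal1d(sin(2 * pi * 20 * t), fs)
  tone_out <- signal1d(sin(2 * pi * 0.25 * t), fs)
  rms <- function(x) sqrt(mean(x^2))
  expect_gte(rms(cwt_band_reconstruct(tone_in, c(10, 40))$values) /
               rms(tone_in$values), 0.9)
  expect_lte(rms(cwt_band_reconstruct(tone_out, c(10, 40))$values) /
               rms(tone_out$values), 0.1)

  # mixture: reconstruction matches an ideal FFT brick-wall band-pass
  mix <- signal1d(sin(2 * pi * 20 * t) + sin(2 * pi * 0.25 * t), fs)
  rec <- cwt_band_reconstruct(mix, c(10, 40))
  X <- fft(mix$values)
  f <- c(seq(0, length(t) / 2), seq(-length(t) / 2 + 1, -1)) * fs / length(t)
  X[abs(f) < 10 | abs(f) > 40] <- 0
  brick <- Re(fft(X, inverse = TRUE) / length(t))
  expect_gte(cor(rec$values, brick), 0.95)
  expect_gte(cor(rec$values, sin(2 * pi * 20 * t)), 0.95)
})

test_that("wavelet reconstruction rejects invalid bands and short signals", {
  sig <- signal1d(rnorm(1200), 120)
  expect_error(cwt_band_reconstruct(sig, c(10, 70)), "Nyquist")
  expect_error(cwt_band_reconstruct(signal1d(rnorm(100), 120), c(10, 40)),
               "2 s")
})

test_that("peak normalization scales to unit maximum and is idempotent", {
  sig <- signal1d(c(0, 2, -4), 1)
  expect_equal(normalize_peak(sig)$values, c(0, 0.5, -1))
  expect_equal(normalize_peak(normalize_peak(sig))$values,
               normalize_peak(sig)$values)
  expect_error(normalize_peak(signal1d(numeric(5), 1)), "all-zero")
})

test_that("normalization does not move the downstream dominant peak", {
  fs <- 40
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  sig <- signal1d(3.7 * sin(2 * pi * 1.2 * t) + 0.5 * rnorm(length(t)), fs)
  r1 <- extract_rate_series(sig, c(0.7, 3), 10)
  r2 <- extract_rate_series(normalize_peak(sig), c(0.7, 3), 10)
  expect_equal(r1$rate, r2$rate)
})

test_that("RMS envelope matches its closed forms and brute-force definition", {
  expect_equal(rms_envelope(signal1d(rep(-3, 100), 10), 7)$values, rep(3, 100))
  # sine of amplitude A over an integer number of periods -> A/sqrt(2)
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  A <- 2.5
  env <- rms_envelope(signal1d(A * sin(2 * pi * 5 * t), fs), 40)$values
  interior <- env[200:800]
  expect_true(all(abs(interior - A / sqrt(2)) < 0.01 * A / sqrt(2)))
  # small-array brute force, centered window with edge shrinkage
  x <- c(1, 2, 3, 4, 5)
  env3 <- rms_envelope(signal1d(x, 1), 3)$values
  expect_equal(env3[3], sqrt((4 + 9 + 16) / 3))
  brute <- function(x, w) sapply(seq_along(x), function(i) {
    idx <- max(1, i - (w - 1) %/% 2):min(length(x), i + w %/% 2)
    sqrt(mean(x[idx]^2))
  })
  set.seed(1)
  for (w in c(1, 2, 3, 4, 7)) {
    x <- rnorm(20)
    expect_equal(rms_envelope(signal1d(x, 1), w)$values, brute(x, w))
  }
  expect_error(rms_envelope(signal1d(x, 1), 0), ">= 1")
  expect_error(rms_envelope(signal1d(x, 1), 40), "length")
})

test_that("Butterworth band-pass removes DC, passes the band center, -3 dB at cutoffs", {
  fs <- 120
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  core <- t > 5 & t < 55  # discard filter edge transients
  dc <- butter_bandpass(signal1d(rep(1, length(t)), fs), c(0.7, 3))
  expect_lte(rms(dc$values[core]), 1e-3)
  fc <- sqrt(0.7 * 3)
  tone <- signal1d(sin(2 * pi * fc * t), fs)
  out <- butter_bandpass(tone, c(0.7, 3))
  expect_gte(rms(out$values[core]) / rms(tone$values[core]), 0.9)
  # single-pass designed magnitude at each cutoff is 1/sqrt(2)
  expect_equal(filter_response(c(0.7, 3), 1, 120, c(0.7, 3)),
               rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(filter_response(c(0.1, 0.7), 1, 25, c(0.1, 0.7)),
               rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_error(butter_bandpass(tone, c(3, 0.7)), "f_lo")
})

test_that("reference preprocessing recovers the reference rates", {
  proto <- constant_protocol(hr = 72, rr = 15, duration = 60, seed = 3)
  ref <- synthesize_reference(proto)
  card <- reference_preprocess(ref, "cardiac")
  expect_equal(oracle_dominant_freq(card$values, card$fs, fmin = 0.5, fmax = 4),
               1.2, tolerance = 0.02)
  resp <- reference_preprocess(ref, "respiratory")
  expect_equal(oracle_dominant_freq(resp$values, resp$fs, fmin = 0.05, fmax = 1),
               0.25, tolerance = 0.02)
  # apnea everywhere: the filtered respiration stays (numerically) silent
  proto_ap <- constant_protocol(duration = 60, apnea = list(c(0, 60)))
  flat <- reference_preprocess(synthesize_reference(proto_ap), "respiratory")
  expect_lte(max(abs(flat$values)), 1e-9)
})

test_that("preprocessing chains preserve length, produce finite output, and band-limit", {
  proto <- constant_protocol(duration = 60, noise = 0.05, seed = 8)
  rec <- synthesize_mechanical(proto)$recording
  n <- length(rec$time_s)
  for (sensor in c("ACC", "GYR")) {
    card <- cardiac_preprocess(rec, sensor)
    resp <- respiratory_preprocess(rec, sensor)
    expect_length(card$values, n)
    expect_length(resp$values, n)
    expect_true(all(is.finite(card$values)))
    expect_true(all(is.finite(resp$values)))
    core <- rec$time_s > 5 & rec$time_s < 55
    expect_gte(band_power_fraction(card$values[core], rec$fs, 0.7, 3), 0.9)
    expect_gte(band_power_fraction(resp$values[core], rec$fs, 0.1, 0.7), 0.9)
  }
})

test_that("the pipeline is scale-equivariant: amplitude does not move the peak", {
  proto <- constant_protocol(duration = 40, noise = 0.05, seed = 9)
  rec <- synthesize_mechanical(proto)$recording
  rec_scaled <- rec
  for (ch in c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"))
    rec_scaled[[ch]] <- 37 * rec[[ch]]
  r1 <- extract_rate_series(cardiac_preprocess(rec, "ACC"), c(0.7, 3), 25)
  r2 <- extract_rate_series(cardiac_preprocess(rec_scaled, "ACC"), c(0.7, 3), 25)
  expect_equal(r1$rate, r2$rate)
})
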