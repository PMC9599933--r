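test_that("sliding-window segmentation obeys the count law", {
  fs <- 40
  sig <- signal1d(rnorm(120 * fs), fs)
  expect_length(segment_windows(sig, 25), 96)   # 120 - 25 + 1
  expect_length(segment_windows(sig, 5), 116)
  expect_length(segment_windows(signal1d(rnorm(25 * fs), fs), 25), 1)
  expect_error(segment_windows(signal1d(rnorm(10 * fs), fs), 25), "exceeds")
  segs <- segment_windows(sig, 25)
  expect_equal(segs[[1]]$center, 12.5)
  expect_equal(diff(sapply(segs, `[[`, "center")), rep(1, 95))
  expect_length(segs[[1]]$values, 25 * fs)
})

test_that("the PSD grid spacing is the configured constant for every rate and length", {
  seg5 <- rnorm(5 * 120)
  res <- sapply(c(120, 250, 25), function(fs)
    welch_psd(rnorm(5 * fs), fs, band = c(0.7, 3))$resolution)
  expect_identical(res[1], res[2])
  expect_identical(res[1], res[3])
  expect_identical(res[1], 1 / 6000)
  for (L in c(5, 25, 55))
    expect_identical(welch_psd(rnorm(L * 120), 120, band = c(0.7, 3))$resolution,
                     1 / 6000)
})

test_that("band-restricted PSD equals the corresponding bins of the full transform", {
  fs <- 20
  x <- rnorm(10 * fs)
  full <- welch_psd(x, fs, resolution = 0.01, band = NULL)
  bandp <- welch_psd(x, fs, resolution = 0.01, band = c(0.7, 3))
  f_full <- psd_frequencies(full)
  sel <- which(f_full >= bandp$f_start - 1e-12 &
                 f_full <= max(psd_frequencies(bandp)) + 1e-12)
  expect_equal(bandp$power, full$power[sel], tolerance = 1e-10)
  expect_equal(psd_frequencies(bandp), f_full[sel], tolerance = 1e-12)
})

test_that("a pure tone is located to grid precision at every window length", {
  fs <- 40
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  for (L in c(15, 25, 35, 45, 55)) {
    psd <- welch_psd(x[1:(L * fs)], fs, band = c(0.7, 3))
    f <- psd_frequencies(psd)
    expect_lte(abs(f[which.max(psd$power)] - 1.2), psd$resolution + 1e-12)
  }
  # at 5 s the negative-frequency image of the tone shifts the fine-grid
  # peak by a small interference bias; it stays within 0.1 bpm
  psd5 <- welch_psd(x[1:(5 * fs)], fs, band = c(0.7, 3))
  f5 <- psd_frequencies(psd5)
  expect_lte(abs(f5[which.max(psd5$power)] - 1.2), 0.1 / 60)
})

test_that("degenerate segments are handled", {
  psd <- welch_psd(numeric(100), 20, resolution = 0.01)
  expect_true(all(psd$power == 0))
  expect_true(is.na(dominant_rate(psd, c(0.7, 3))))
  expect_error(welch_psd(numeric(0), 20), "empty")
  expect_error(welch_psd(rnorm(100), 20, resolution = 1), "coarsen")
})

test_that("dominant-rate picking: conversion, larger peak wins, ties go low", {
  fs <- 25
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  expect_equal(dominant_rate(welch_psd(sin(2 * pi * 1.2 * t), fs,
                                       band = c(0.7, 3)), c(0.7, 3)),
               72, tolerance = 0.01)
  expect_equal(dominant_rate(welch_psd(sin(2 * pi * 0.25 * t), fs,
                                       band = c(0.1, 0.7)), c(0.1, 0.7)),
               15, tolerance = 0.01)
  two <- sin(2 * pi * 1 * t) + 0.5 * sin(2 * pi * 2 * t)
  expect_equal(dominant_rate(welch_psd(two, fs, band = c(0.7, 3)), c(0.7, 3)),
               60, tolerance = 0.01)
  # exact tie: the lower frequency is reported
  psd_tie <- structure(list(power = c(0, 1, 1, 0), f_start = 1,
                            resolution = 0.1, nfft = 1000, fs = 25,
                            total_power = 1),
                       class = "psd_estimate")
  expect_equal(dominant_rate(psd_tie, c(1, 1.3)), 60 * 1.1)
  expect_error(dominant_rate(psd_tie, c(5, 6)), "intersect")
})

test_that("rate series: count law, 1 s spacing, rates confined to the band", {
  fs <- 40
  t <- seq(0, 90 - 1 / fs, by = 1 / fs)
  sig <- signal1d(sin(2 * pi * 1.5 * t) + 0.3 * rnorm(length(t)), fs)
  for (L in c(5, 25, 55)) {
    rs <- extract_rate_series(sig, c(0.7, 3), L)
    expect_equal(nrow(rs), 90 - L + 1)
    expect_equal(diff(rs$window_center_s), rep(1, nrow(rs) - 1))
    ok <- rs$rate[rs$valid]
    expect_true(all(ok >= 42 & ok <= 180))
  }
})

test_that("mechanical and reference series share window centers for pairing", {
  t120 <- seq(0, 60 - 1 / 120, by = 1 / 120)
  t25 <- seq(0, 60 - 1 / 25, by = 1 / 25)
  a <- extract_rate_series(signal1d(sin(2 * pi * 0.3 * t120), 120),
                           c(0.1, 0.7), 15)
  b <- extract_rate_series(signal1d(sin(2 * pi * 0.3 * t25), 25),
                           c(0.1, 0.7), 15)
  expect_identical(a$window_center_s, b$window_center_s)
})

test_that("single-tone series recover 60x the tone frequency at every length", {
  fs <- 40
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  sig <- signal1d(sin(2 * pi * 1.2 * t), fs)
  for (L in c(15, 35, 55)) {
    rs <- extract_rate_series(sig, c(0.7, 3), L)
    expect_true(all(abs(rs$rate - 72) <= 60 * 1 / 6000 + 1e-9))
  }
  rs5 <- extract_rate_series(sig, c(0.7, 3), 5)
  expect_true(all(abs(rs5$rate - 72) <= 0.1))  # interference bias at 5 s
})

test_that("longer windows attenuate tracked rate variations", {
  # frequency-modulated tone: 70 +/- 10 bpm over a 30 s modulation period;
  # winner-take-all peak picking follows the excursions at 5 s but averages
  # them away as the window grows
  fs <- 40
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  inst <- (70 + 10 * sin(2 * pi * t / 30)) / 60
  x <- sin(2 * pi * cumsum(inst) / fs)
  sig <- signal1d(x, fs)
  excursion <- sapply(c(5, 15, 25), function(L) {
    rs <- extract_rate_series(sig, c(0.7, 3), L)
    diff(range(rs$rate, na.rm = TRUE))
  })
  expect_true(all(diff(excursion) < 0))
  expect_gt(excursion[1], 10)  # short windows track most of the +/-10 swing
})

test_that("windows inside a breath-hold are flagged invalid in a clean reference", {
  proto <- constant_protocol(rr = 15, duration = 120, apnea = list(c(80, 120)))
  resp <- reference_preprocess(synthesize_reference(proto), "respiratory")
  rs <- extract_rate_series(resp, c(0.1, 0.7), 15)
  deep <- rs$window_center_s > 100  # windows fully inside the hold
  expect_true(any(!rs$valid))
  expect_true(all(!rs$valid[deep]))
  expect_true(all(is.na(rs$rate[!rs$valid])))
  expect_true(all(rs$valid[rs$window_center_s < 70]))
})
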