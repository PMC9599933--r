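# Synthetic chest-kinematics generator.
#
# The mechanical model: each heartbeat deposits a short high-frequency
# vibration packet (Gaussian-windowed sinusoid, carrier inside 10-40 Hz) on
# the chest surface, superimposed on a slow respiratory oscillation at the
# instantaneous breathing rate, plus broadband posture-dependent noise. The
# designated analysis channels (accelerometer z, gyroscope y) carry the
# largest component amplitudes; the remaining axes carry attenuated copies
# with independent noise so that axis selection is testable.

cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (head(y, -1) + tail(y, -1)) / 2))
}

#' Beat instants from an instantaneous heart-rate trajectory
#'
#' Integrates the instantaneous rate so that consecutive inter-beat intervals
#' equal 60/HR(t) along the trajectory: beats occur where the cumulative
#' cardiac phase \eqn{\int HR(t)/60\,dt} crosses successive integers.
#'
#' @param hr_trajectory constant, function or time/value table (bpm); must be
#'   strictly positive over the recording.
#' @param duration recording duration (s); beats are strictly inside
#'   `[0, duration)`.
#' @param phase time of the first beat (s), in `[0, 60/HR(0))`. The cohort
#'   generator draws it per seed so packets never align systematically with
#'   window boundaries.
#' @param dt integration grid step (s) for the phase integral.
#' @return numeric vector of beat times (s).
#' @export
beat_times_from_hr <- function(hr_trajectory, duration, phase = 0, dt = 1e-3) {
  traj <- as_trajectory(hr_trajectory, duration)
  if (any(traj$value <= 0)) stop("heart-rate trajectory must be positive")
  tg <- seq(0, duration, by = dt)
  hr0 <- eval_trajectory(traj, 0)
  if (phase < 0 || phase >= 60 / hr0)
    stop("phase must lie in [0, 60/HR(0))")
  ph <- cumtrapz(tg, eval_trajectory(traj, tg) / 60)
  p0 <- stats::approx(tg, ph, xout = phase)$y
  kmax <- floor(ph[length(ph)] - p0)
  if (kmax < 0) return(numeric(0))
  bt <- stats::approx(ph, tg, xout = p0 + 0:kmax, ties = "ordered")$y
  bt[bt < duration & !is.na(bt)]
}

# Beat times implied by a protocol: the first-beat phase is the first random
# draw under the protocol seed, so the mechanical and reference generators
# agree on beat instants by construction.
protocol_beat_times <- function(protocol) {
  dur <- protocol_duration(protocol)
  hr0 <- eval_trajectory(protocol$hr_trajectory, 0)
  phase <- with_seed(protocol$seed, runif(1, 0, 60 / hr0))
  beat_times_from_hr(protocol$hr_trajectory, dur, phase = phase)
}

# Respiratory oscillation amplitude mask: 1 during quiet breathing, 0 inside
# apnea, with a half-cosine taper of `taper` seconds entering each hold so the
# amplitude drop introduces no spectral discontinuity.
apnea_mask <- function(t, apnea_intervals, taper = 0.5) {
  m <- rep(1, length(t))
  for (iv in apnea_intervals) {
    m[t >= iv[1] & t < iv[2]] <- 0
    ramp <- t >= iv[1] - taper & t < iv[1]
    m[ramp] <- 0.5 * (1 + cos(pi * (t[ramp] - (iv[1] - taper)) / taper))
  }
  m
}

# One cardiac packet per beat: Gaussian-windowed sinusoid truncated to
# +-half_width (120 ms total at the defaults). The carrier sits at the
# midpoint of the 10-40 Hz analysis band and the envelope SD is wide enough
# that >=95% of the packet's spectral power stays inside that band.
cardiac_packet_train <- function(t, beats, carrier = 25, sigma = 0.024,
                                 half_width = 0.06) {
  x <- numeric(length(t))
  fs <- 1 / (t[2] - t[1])
  half <- ceiling(half_width * fs)
  for (b in beats) {
    i0 <- max(1L, floor(b * fs) - half)
    i1 <- min(length(t), floor(b * fs) + half)
    idx <- i0:i1
    x[idx] <- x[idx] +
      exp(-(t[idx] - b)^2 / (2 * sigma^2)) * cos(2 * pi * carrier * (t[idx] - b))
  }
  x
}

#' Synthesize the mechanical (IMU) recording for a protocol
#'
#' Produces the six-channel inertial recording plus the 1 Hz ground truth.
#' Channel model: `acc_z` and `gyr_y` (the analysis axes) carry the full
#' cardiac packet train and respiratory oscillation; the remaining axes carry
#' 0.3-attenuated copies; every channel receives independent Gaussian noise
#' with the posture's SD. Identical `(protocol, fs)` yield bit-identical
#' output.
#'
#' @param protocol a [subject_protocol()].
#' @param fs sampling rate (Hz), 120 by default.
#' @param cardiac_amp,resp_amp component amplitudes on `acc_z` (signal units).
#' @param gyr_scale relative amplitude of the gyroscope analysis axis.
#' @param carrier,sigma packet carrier frequency (Hz, inside 10--40) and
#'   Gaussian envelope SD (s); the defaults (25 Hz, 24 ms) keep at least 95%
#'   of the packet power inside 10--40 Hz with a packet no longer than
#'   120 ms.
#' @return list with elements `recording` (class `inertial_recording`) and
#'   `truth` (class `ground_truth`).
#' @export
synthesize_mechanical <- function(protocol, fs = 120, cardiac_amp = 1,
                                  resp_amp = 0.5, gyr_scale = 0.9,
                                  carrier = 25, sigma = 0.024) {
  stopifnot(inherits(protocol, "subject_protocol"), fs > 2 * 40)
  dur <- protocol_duration(protocol)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  beats <- protocol_beat_times(protocol)
  card <- cardiac_packet_train(t, beats, carrier, sigma)
  resp <- sin(2 * pi * cumtrapz(t, eval_trajectory(protocol$rr_trajectory, t) / 60)) *
    apnea_mask(t, protocol$apnea_intervals)
  sd_t <- rep(0, length(t))
  t0 <- 0
  for (i in seq_len(nrow(protocol$segments))) {
    seg <- protocol$segments[i, ]
    sd_t[t >= t0 & t < t0 + seg$duration] <- protocol$noise_sd[[seg$posture]]
    t0 <- t0 + seg$duration
  }
  acc_base <- cardiac_amp * card + resp_amp * resp
  gyr_base <- gyr_scale * (cardiac_amp * card + resp_amp * resp)
  chans <- with_seed(protocol$seed, {
    runif(1)  # burn the first-beat phase draw shared with the reference
    noise <- function() rnorm(length(t), 0, 1) * sd_t
    list(acc_x = 0.3 * acc_base + noise(),
         acc_y = 0.3 * acc_base + noise(),
         acc_z = acc_base + noise(),
         gyr_x = 0.3 * gyr_base + noise(),
         gyr_y = gyr_base + noise(),
         gyr_z = 0.3 * gyr_base + noise())
  })
  rec <- structure(
    c(list(time_s = t), chans, list(fs = fs)),
    class = "inertial_recording")
  list(recording = rec, truth = ground_truth(protocol))
}

#' Synthesize the reference (gold-standard) recording for a protocol
#'
#' The ECG-like channel (250 Hz by default) has one sharp R-like spike per
#' beat at the same beat instants as the mechanical simulation, plus a
#' low-amplitude beat-locked baseline oscillation that stands in for the
#' T-wave energy of a real ECG (it gives the band-passed reference a dominant
#' spectral fundamental, as real recordings have). The respiration channel
#' (25 Hz) is a smooth oscillation at the instantaneous RR, flat during
#' breath-holds.
#'
#' @param protocol a [subject_protocol()].
#' @param fs_ecg,fs_resp channel sampling rates (Hz).
#' @param ecg_noise_sd,resp_noise_sd optional seeded Gaussian noise SDs; the
#'   defaults of 0 model a clean clinical reference.
#' @return object of class `reference_recording`: list with `ecg` (`time_s`,
#'   `ecg`, `fs`) and `resp` (`time_s`, `resp`, `fs`).
#' @export
synthesize_reference <- function(protocol, fs_ecg = 250, fs_resp = 25,
                                 ecg_noise_sd = 0, resp_noise_sd = 0) {
  stopifnot(inherits(protocol, "subject_protocol"))
  dur <- protocol_duration(protocol)
  beats <- protocol_beat_times(protocol)
  te <- seq(0, dur - 1 / fs_ecg, by = 1 / fs_ecg)
  # beat-locked fundamental: cardiac phase aligned so cos peaks at beats
  ph <- cumtrapz(te, eval_trajectory(protocol$hr_trajectory, te) / 60)
  ph0 <- if (length(beats)) stats::approx(te, ph, xout = beats[1])$y else 0
  ecg <- 0.25 * cos(2 * pi * (ph - ph0))
  fse <- fs_ecg
  for (b in beats) {
    i0 <- max(0L, floor((b - 0.1) * fse)); i1 <- min(length(te) - 1L, ceiling((b + 0.1) * fse))
    idx <- (i0:i1) + 1L
    ecg[idx] <- ecg[idx] + exp(-(te[idx] - b)^2 / (2 * 0.02^2))
  }
  tr <- seq(0, dur - 1 / fs_resp, by = 1 / fs_resp)
  resp <- sin(2 * pi * cumtrapz(tr, eval_trajectory(protocol$rr_trajectory, tr) / 60)) *
    apnea_mask(tr, protocol$apnea_intervals)
  noise <- with_seed(protocol$seed + 1L, list(
    ecg = rnorm(length(te), 0, 1) * ecg_noise_sd,
    resp = rnorm(length(tr), 0, 1) * resp_noise_sd))
  structure(
    list(ecg = list(time_s = te, ecg = ecg + noise$ecg, fs = fs_ecg),
         resp = list(time_s = tr, resp = resp + noise$resp, fs = fs_resp)),
    class = "reference_recording")
}

#' Synthesize one complete subject
#'
#' Convenience wrapper returning the mechanical recording, the reference
#' recording and the ground truth for a protocol.
#'
#' @inheritParams synthesize_mechanical
#' @param ... passed to [synthesize_mechanical()].
#' @return list with `recording`, `reference`, `truth`, `protocol`.
#' @export
synthesize_subject <- function(protocol, fs = 120, ...) {
  mech <- synthesize_mechanical(protocol, fs = fs, ...)
  list(recording = mech$recording,
       reference = synthesize_reference(protocol),
       truth = mech$truth,
       protocol = protocol)
}

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> %d samples at %g Hz (%.1f s), channels: %s\n",
              length(x$time_s), x$fs, length(x$time_s) / x$fs,
              paste(setdiff(names(x), c("time_s", "fs")), collapse = ", ")))
  invisible(x)
}

#' @export
print.reference_recording <- function(x, ...) {
  cat(sprintf("<reference_recording> ecg: %d samples at %g Hz; resp: %d samples at %g Hz\n",
              length(x$ecg$time_s), x$ecg$fs, length(x$resp$time_s), x$resp$fs))
  invisible(x)
}
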