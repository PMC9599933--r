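#' Piecewise-linear rate trajectories
#'
#' A trajectory describes an instantaneous rate (HR in bpm or RR in BrPM) as a
#' function of time. Internally it is a two-column `data.frame` (`time`,
#' `value`) interpolated linearly; evaluation outside the tabulated range
#' clamps to the end values.
#'
#' @param x a single number (constant rate), a function of time, or a
#'   `data.frame` with columns `time` and `value`.
#' @param duration recording duration in seconds, used to tabulate constant
#'   and functional inputs.
#' @return a `data.frame` with columns `time` (s) and `value`.
#' @export
as_trajectory <- function(x, duration) {
  if (is.data.frame(x)) {
    if (!all(c("time", "value") %in% names(x)))
      stop("trajectory data.frame needs columns 'time' and 'value'")
    out <- x[order(x$time), c("time", "value")]
  } else if (is.function(x)) {
    tt <- seq(0, duration, by = 1)
    out <- data.frame(time = tt, value = x(tt))
  } else if (is.numeric(x) && length(x) == 1L) {
    out <- data.frame(time = c(0, duration), value = c(x, x))
  } else {
    stop("trajectory must be a constant, a function, or a time/value table")
  }
  if (anyNA(out$value) || any(!is.finite(out$value)))
    stop("trajectory contains non-finite values")
  out
}

#' Evaluate a trajectory at given times
#'
#' @param traj a trajectory table from [as_trajectory()].
#' @param t times in seconds.
#' @return rate values at `t`, linearly interpolated, clamped at the ends.
#' @export
eval_trajectory <- function(traj, t) {
  if (nrow(traj) == 1L) return(rep(traj$value, length(t)))
  stats::approx(traj$time, traj$value, xout = t, rule = 2)$y
}

#' Subject measurement protocol
#'
#' Bundles everything the synthetic generator needs to emit one subject's
#' recordings: the ordered posture segments, the instantaneous HR and RR
#' trajectories, breath-hold (apnea) intervals, per-posture broadband noise
#' levels and the random seed. The default study protocol is three ~2 min
#' at-rest postures (sitting, standing, lying), each ending with a 20 s
#' breath-hold.
#'
#' @param segments `data.frame` with columns `posture` (character) and
#'   `duration` (s, > 0), in recording order.
#' @param hr_trajectory,rr_trajectory constant, function or time/value table
#'   (see [as_trajectory()]). HR must stay within 42--180 bpm (inside the
#'   0.7--3 Hz cardiac analysis band), RR within 6--42 BrPM (inside
#'   0.1--0.7 Hz).
#' @param apnea_intervals list of `c(start, end)` pairs in seconds during
#'   which respiratory motion amplitude is zero.
#' @param noise_sd named numeric vector mapping each posture label to the
#'   standard deviation of the broadband Gaussian sensor noise (signal units).
#' @param seed integer seed; identical protocols yield bit-identical
#'   recordings.
#' @return an object of class `subject_protocol`.
#' @export
subject_protocol <- function(segments, hr_trajectory, rr_trajectory,
                             apnea_intervals = list(), noise_sd, seed = 1L) {
  if (!is.data.frame(segments) || !all(c("posture", "duration") %in% names(segments)))
    stop("segments must be a data.frame with columns 'posture' and 'duration'")
  if (any(segments$duration <= 0)) stop("all segment durations must be > 0")
  total <- sum(segments$duration)
  hr <- as_trajectory(hr_trajectory, total)
  rr <- as_trajectory(rr_trajectory, total)
  if (any(hr$value < 42 | hr$value > 180))
    stop("hr_trajectory must stay within [42, 180] bpm")
  if (any(rr$value < 6 | rr$value > 42))
    stop("rr_trajectory must stay within [6, 42] BrPM")
  for (iv in apnea_intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2] || iv[1] < 0 || iv[2] > total)
      stop("apnea intervals must be (start, end) pairs inside the recording")
  }
  missing_sd <- setdiff(unique(segments$posture), names(noise_sd))
  if (length(missing_sd))
    stop("noise_sd missing posture(s): ", paste(missing_sd, collapse = ", "))
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  structure(
    list(segments = segments, hr_trajectory = hr, rr_trajectory = rr,
         apnea_intervals = apnea_intervals,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "subject_protocol")
}

#' @export
print.subject_protocol <- function(x, ...) {
  cat("<subject_protocol> seed", x$seed, "\n")
  cat("  segments:", paste(sprintf("%s (%gs)", x$segments$posture,
                                   x$segments$duration), collapse = ", "), "\n")
  cat("  HR range:", paste(round(range(x$hr_trajectory$value), 1), collapse = "-"),
      "bpm; RR range:",
      paste(round(range(x$rr_trajectory$value), 1), collapse = "-"), "BrPM\n")
  cat("  apnea intervals:", length(x$apnea_intervals),
      " noise SD:", paste(sprintf("%s=%g", names(x$noise_sd), x$noise_sd),
                          collapse = ", "), "\n")
  invisible(x)
}

# Default per-posture broadband noise SD, in units of the cardiac packet
# amplitude. Ordering (lying < sitting < standing) mirrors the observed
# posture-dependent degradation of chest-worn IMU signal quality.
default_noise_sd <- c(sitting = 0.05, standing = 0.15, lying = 0.03)

#' Default randomized study protocol
#'
#' Builds a protocol mirroring the study design: one ~120 s segment per
#' requested posture, each ending with a 20 s breath-hold, with smooth
#' seeded-random HR and RR trajectories. HR wanders within 60--80 bpm and RR
#' within roughly 9--21 BrPM (quiet resting ranges).
#'
#' @param seed integer seed controlling the trajectories, the cardiac phase
#'   and the noise realization.
#' @param postures character vector of posture labels, one segment each.
#' @param segment_s duration of each posture segment (s).
#' @param apnea_s terminal breath-hold duration per segment (s); 0 disables.
#' @param noise_sd named per-posture noise SD; defaults to
#'   lying 0.03 < sitting 0.05 < standing 0.15 (cardiac-amplitude units).
#' @return a [subject_protocol()].
#' @export
default_protocol <- function(seed = 1L,
                             postures = c("sitting", "standing", "lying"),
                             segment_s = 120, apnea_s = 20,
                             noise_sd = default_noise_sd) {
  stopifnot(segment_s > 0, apnea_s >= 0, apnea_s < segment_s)
  total <- segment_s * length(postures)
  pars <- with_seed(seed, list(
    hr_base = runif(1, 66, 74), hr_amp = runif(1, 4, 6),
    hr_per = runif(1, 60, 100), hr_ph = runif(1, 0, 2 * pi),
    rr_base = runif(1, 14, 16), rr_amp = runif(1, 3.5, 4.5),
    rr_per = runif(1, 100, 160), rr_ph = runif(1, 0, 2 * pi)))
  hr_fun <- function(t) pars$hr_base + pars$hr_amp * sin(2 * pi * t / pars$hr_per + pars$hr_ph)
  rr_fun <- function(t) pars$rr_base + pars$rr_amp * sin(2 * pi * t / pars$rr_per + pars$rr_ph)
  apnea <- list()
  if (apnea_s > 0) {
    apnea <- lapply(seq_along(postures), function(i)
      c(i * segment_s - apnea_s, i * segment_s))
  }
  subject_protocol(
    segments = data.frame(posture = postures, duration = segment_s),
    hr_trajectory = hr_fun, rr_trajectory = rr_fun,
    apnea_intervals = apnea,
    noise_sd = noise_sd[unique(postures)],
    seed = seed)
}

#' Total protocol duration in seconds
#' @param protocol a [subject_protocol()].
#' @export
protocol_duration <- function(protocol) sum(protocol$segments$duration)

#' Ground-truth rate table for a protocol
#'
#' Samples the protocol's HR/RR trajectories on a 1 s grid and flags time
#' points lying inside an apnea interval. This is the generative truth that
#' parameter-recovery checks compare against.
#'
#' @param protocol a [subject_protocol()].
#' @return `data.frame` with columns `time_s`, `hr_bpm`, `rr_brpm`, `apnea`
#'   (0/1), class `ground_truth`.
#' @export
ground_truth <- function(protocol) {
  tt <- seq(0, protocol_duration(protocol) - 1, by = 1)
  ap <- rep(FALSE, length(tt))
  for (iv in protocol$apnea_intervals) ap <- ap | (tt >= iv[1] & tt < iv[2])
  structure(
    data.frame(time_s = tt,
               hr_bpm = eval_trajectory(protocol$hr_trajectory, tt),
               rr_brpm = eval_trajectory(protocol$rr_trajectory, tt),
               apnea = as.integer(ap)),
    class = c("ground_truth", "data.frame"))
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
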