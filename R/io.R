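# CSV readers/writers for the recording streams, YAML protocol/config
# handling, and run logging. All time stamps are seconds from recording
# start; mechanical and reference streams are assumed synchronized at t = 0
# (the simulator guarantees it).

imu_channels <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  for (col in required) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-finite value in column '%s' at row %d", path, col, bad[1]))
  }
}

check_uniform_time <- function(time_s, path) {
  if (length(time_s) < 2) stop(sprintf("%s: fewer than 2 samples", path))
  dt <- diff(time_s)
  if (any(dt <= 0)) stop(sprintf("%s: non-monotonic time at row %d", path, which(dt <= 0)[1] + 1L))
  fs <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs)) >= 1 / (2 * fs))
    stop(sprintf("%s: time stamps are not uniform (jitter >= half a sample)", path))
  # snap to an integer rate when the data are that close to one
  if (abs(fs - round(fs)) < 1e-6) fs <- round(fs)
  fs
}

#' Write / read an inertial recording as CSV
#'
#' Schema: `time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`, one row per
#' sample at the uniform IMU rate. Round-tripping reproduces values to better
#' than 1e-9 relative.
#'
#' @param rec an `inertial_recording`.
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `inertial_recording`.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time_s = rec$time_s)
  for (ch in imu_channels) df[[ch]] <- rec[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop(path, ": empty file")
  check_columns(df, c("time_s", imu_channels), path)
  fs <- check_uniform_time(df$time_s, path)
  structure(c(list(time_s = df$time_s), as.list(df[imu_channels]), list(fs = fs)),
            class = "inertial_recording")
}

#' Write / read a reference recording (ECG + respiration CSVs)
#'
#' Two files: `time_s, ecg` at the ECG rate and `time_s, resp` at the
#' respiration rate.
#'
#' @param ref a `reference_recording`.
#' @param ecg_path,resp_path CSV file paths.
#' @return `read_reference` returns a `reference_recording`.
#' @export
write_reference <- function(ref, ecg_path, resp_path) {
  utils::write.csv(data.frame(time_s = ref$ecg$time_s, ecg = ref$ecg$ecg),
                   ecg_path, row.names = FALSE)
  utils::write.csv(data.frame(time_s = ref$resp$time_s, resp = ref$resp$resp),
                   resp_path, row.names = FALSE)
  invisible(c(ecg_path, resp_path))
}

#' @rdname write_reference
#' @export
read_reference <- function(ecg_path, resp_path) {
  for (p in c(ecg_path, resp_path)) if (!file.exists(p)) stop("no such file: ", p)
  e <- utils::read.csv(ecg_path)
  r <- utils::read.csv(resp_path)
  if (nrow(e) == 0) stop(ecg_path, ": empty file")
  if (nrow(r) == 0) stop(resp_path, ": empty file")
  check_columns(e, c("time_s", "ecg"), ecg_path)
  check_columns(r, c("time_s", "resp"), resp_path)
  structure(
    list(ecg = list(time_s = e$time_s, ecg = e$ecg,
                    fs = check_uniform_time(e$time_s, ecg_path)),
         resp = list(time_s = r$time_s, resp = r$resp,
                     fs = check_uniform_time(r$time_s, resp_path))),
    class = "reference_recording")
}

#' Write / read a ground-truth table as CSV
#'
#' Schema: `time_s, hr_bpm, rr_brpm, apnea` at 1 Hz.
#' @param truth a `ground_truth` table.
#' @param path CSV file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("time_s", "hr_bpm", "rr_brpm", "apnea"), path)
  structure(df, class = c("ground_truth", "data.frame"))
}

#' Write / read a subject protocol as YAML
#'
#' @param protocol a [subject_protocol()].
#' @param path YAML file path.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(list(
    segments = list(posture = as.list(protocol$segments$posture),
                    duration = as.list(protocol$segments$duration)),
    hr_trajectory = list(time = protocol$hr_trajectory$time,
                         value = protocol$hr_trajectory$value),
    rr_trajectory = list(time = protocol$rr_trajectory$time,
                         value = protocol$rr_trajectory$value),
    apnea_intervals = lapply(protocol$apnea_intervals, as.numeric),
    noise_sd = as.list(protocol$noise_sd),
    seed = protocol$seed), path, precision = 15L)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  subject_protocol(
    segments = data.frame(posture = unlist(y$segments$posture),
                          duration = unlist(y$segments$duration)),
    hr_trajectory = data.frame(time = unlist(y$hr_trajectory$time),
                               value = unlist(y$hr_trajectory$value)),
    rr_trajectory = data.frame(time = unlist(y$rr_trajectory$time),
                               value = unlist(y$rr_trajectory$value)),
    apnea_intervals = lapply(y$apnea_intervals, unlist),
    noise_sd = unlist(y$noise_sd),
    seed = y$seed)
}

#' Pipeline configuration
#'
#' Holds every analysis constant: the selected axes (accelerometer z,
#' gyroscope y), the 10--40 Hz wavelet reconstruction band, the 40-sample RMS
#' envelope window, the 0.7--3 Hz cardiac and 0.1--0.7 Hz respiratory
#' Butterworth bands (order 1), the six sliding-window lengths 5--55 s with a
#' 1 s step, the constant 0.166 mHz (0.01 per-minute) PSD grid, and the 1.96
#' limits-of-agreement multiplier.
#'
#' @param ... overrides for any default field.
#' @return a list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    acc_axis = "z", gyr_axis = "y",
    cardiac_recon_band = c(10, 40),
    envelope_window = 40L,
    cardiac_band = c(0.7, 3),
    resp_band = c(0.1, 0.7),
    filter_order = 1L,
    window_lengths = c(5, 15, 25, 35, 45, 55),
    step = 1,
    psd_resolution = 0.01 / 60,
    loa_multiplier = 1.96)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' @rdname default_config
#' @param config a `pipeline_config` to validate.
#' @export
validate_config <- function(config) {
  for (band in c("cardiac_recon_band", "cardiac_band", "resp_band")) {
    b <- config[[band]]
    if (length(b) != 2 || b[1] >= b[2] || b[1] <= 0)
      stop(band, " must be an ordered positive pair (low < high)")
  }
  if (config$psd_resolution <= 0) stop("psd_resolution must be > 0")
  if (config$step <= 0 || config$step > min(config$window_lengths))
    stop("step must be positive and no larger than the smallest window")
  if (config$envelope_window < 1) stop("envelope_window must be >= 1")
  if (config$filter_order < 1) stop("filter_order must be >= 1")
  config
}

#' Load / save a pipeline configuration as YAML
#'
#' The YAML fields are exactly the [default_config()] field names; absent
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(default_config, y)
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Run logging
#'
#' Writes `timestamp level message` lines to stderr and, when the option
#' `imuvitals.log_file` is set, appends them to that file.
#'
#' @param level one of "INFO", "WARN", "ERROR".
#' @param ... message parts, pasted together.
#' @export
vitals_log <- function(level = "INFO", ...) {
  line <- sprintf("%s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, paste0(..., collapse = ""))
  message(line)
  log_file <- getOption("imuvitals.log_file")
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

# Echo every constant actually used into the run log.
log_config <- function(config) {
  for (nm in names(config))
    vitals_log("INFO", "config ", nm, " = ", paste(config[[nm]], collapse = ", "))
  invisible(config)
}
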