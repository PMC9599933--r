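# Study orchestration: simulate a cohort, run both preprocessing chains for
# both sensors over every posture segment and window length, and produce the
# agreement report. Each posture segment (~120 s) is preprocessed and
# analyzed separately, matching the per-posture structure of the protocol.

slice_stream <- function(time_s, values, fs, t0, t1) {
  keep <- time_s >= t0 & time_s < t1
  list(time_s = time_s[keep] - t0, values = values[keep], fs = fs)
}

#' Split a subject's recordings into posture segments
#'
#' @param rec an `inertial_recording` spanning the whole protocol.
#' @param ref the matching `reference_recording`.
#' @param protocol the [subject_protocol()] that generated them.
#' @return named list (one element per segment, named by posture) of lists
#'   with re-zeroed `recording` and `reference`.
#' @export
split_posture_segments <- function(rec, ref, protocol) {
  out <- list()
  t0 <- 0
  for (i in seq_len(nrow(protocol$segments))) {
    seg <- protocol$segments[i, ]
    t1 <- t0 + seg$duration
    chans <- lapply(rec[imu_channels], function(v)
      v[rec$time_s >= t0 & rec$time_s < t1])
    tsel <- rec$time_s[rec$time_s >= t0 & rec$time_s < t1] - t0
    rseg <- structure(c(list(time_s = tsel), chans, list(fs = rec$fs)),
                      class = "inertial_recording")
    e <- slice_stream(ref$ecg$time_s, ref$ecg$ecg, ref$ecg$fs, t0, t1)
    r <- slice_stream(ref$resp$time_s, ref$resp$resp, ref$resp$fs, t0, t1)
    refseg <- structure(
      list(ecg = list(time_s = e$time_s, ecg = e$values, fs = e$fs),
           resp = list(time_s = r$time_s, resp = r$values, fs = r$fs)),
      class = "reference_recording")
    out[[seg$posture]] <- list(recording = rseg, reference = refseg,
                               posture = seg$posture)
    t0 <- t1
  }
  out
}

#' Extract every rate series for one posture segment
#'
#' Runs the cardiac chain on both sensors and the ECG, and the respiratory
#' chain on both sensors and the respiration waveform, then the sliding
#' window spectral estimator for every requested window length. Window
#' lengths longer than the segment are skipped with a logged warning.
#'
#' @param rec,ref segment recordings (see [split_posture_segments()]).
#' @param config a [default_config()].
#' @param windows window lengths (s) to analyze.
#' @param sensors mechanical sensors to include (`"acc"`, `"gyr"`).
#' @return long `data.frame` with columns `posture` (NA here), `vital`,
#'   `source`, `window_s`, `center_s`, `rate`, `valid`.
#' @export
process_segment <- function(rec, ref, config = default_config(),
                            windows = config$window_lengths,
                            sensors = c("acc", "gyr")) {
  T_s <- floor(length(rec$time_s) / rec$fs)
  usable <- windows[windows <= T_s]
  if (length(usable) < length(windows))
    vitals_log("WARN", "segment of ", T_s, " s: skipping window length(s) ",
               paste(setdiff(windows, usable), collapse = ", "), " s")
  streams <- list()
  for (s in sensors) {
    streams[[paste0("hr.", s)]] <- cardiac_preprocess(rec, toupper(s), config)
    streams[[paste0("rr.", s)]] <- respiratory_preprocess(rec, toupper(s), config)
  }
  streams[["hr.ref"]] <- reference_preprocess(ref, "cardiac", config)
  streams[["rr.ref"]] <- reference_preprocess(ref, "respiratory", config)
  out <- list()
  for (nm in names(streams)) {
    vital <- sub("\\..*", "", nm)
    source <- sub(".*\\.", "", nm)
    band <- if (vital == "hr") config$cardiac_band else config$resp_band
    for (L in usable) {
      rs <- extract_rate_series(streams[[nm]], band, L, config, source = source)
      out[[length(out) + 1L]] <- data.frame(
        vital = vital, source = source, window_s = L,
        center_s = rs$window_center_s, rate = rs$rate, valid = rs$valid)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full pipeline for one simulated subject (in memory)
#'
#' @param subject output of [synthesize_subject()].
#' @param config a [default_config()].
#' @param windows,sensors as in [process_segment()].
#' @param subject_id label stored in the result.
#' @return long estimates table (adds `subject` and `posture` columns),
#'   suitable for [build_report()].
#' @export
process_subject <- function(subject, config = default_config(),
                            windows = config$window_lengths,
                            sensors = c("acc", "gyr"),
                            subject_id = "s1") {
  segs <- split_posture_segments(subject$recording, subject$reference,
                                 subject$protocol)
  out <- lapply(segs, function(sg) {
    df <- process_segment(sg$recording, sg$reference, config, windows, sensors)
    df$posture <- sg$posture
    df
  })
  df <- do.call(rbind, c(out, make.row.names = FALSE))
  df$subject <- subject_id
  df[, c("subject", "posture", "vital", "source", "window_s",
         "center_s", "rate", "valid")]
}

subject_dirs <- function(dir) {
  d <- list.dirs(dir, recursive = FALSE)
  sort(d[grepl("subject_\\d+$", d)])
}

#' Simulate a cohort to disk
#'
#' Writes, per subject, `imu.csv` (120 Hz six-channel recording), `ecg.csv`
#' (250 Hz), `resp.csv` (25 Hz), `truth.csv` (1 Hz ground truth) and
#' `protocol.yaml`. Subject seeds are derived deterministically from the
#' cohort seed.
#'
#' @param outdir output directory (created if needed).
#' @param n_subjects cohort size (the emulated study used 11).
#' @param seed cohort seed.
#' @param postures,segment_s,apnea_s,noise_sd protocol settings, see
#'   [default_protocol()].
#' @return invisibly, the vector of subject directories.
#' @export
simulate_cohort <- function(outdir, n_subjects = 11, seed = 1,
                            postures = c("sitting", "standing", "lying"),
                            segment_s = 120, apnea_s = 20,
                            noise_sd = default_noise_sd) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(n_subjects)
  for (i in seq_len(n_subjects)) {
    proto <- default_protocol(seed = seed * 1000 + i, postures = postures,
                              segment_s = segment_s, apnea_s = apnea_s,
                              noise_sd = noise_sd)
    subj <- synthesize_subject(proto)
    d <- file.path(outdir, sprintf("subject_%02d", i))
    dir.create(d, showWarnings = FALSE)
    write_recording(subj$recording, file.path(d, "imu.csv"))
    write_reference(subj$reference, file.path(d, "ecg.csv"),
                    file.path(d, "resp.csv"))
    write_ground_truth(subj$truth, file.path(d, "truth.csv"))
    write_protocol(proto, file.path(d, "protocol.yaml"))
    dirs[i] <- d
    vitals_log("INFO", "simulated ", d)
  }
  invisible(dirs)
}

#' Extract rate series for a simulated cohort on disk
#'
#' Reads each subject directory written by [simulate_cohort()], runs both
#' chains and writes one long `rates.csv` per subject.
#'
#' @param indir cohort directory.
#' @param outdir output directory for the rate tables.
#' @param config a [default_config()].
#' @param windows,sensors as in [process_segment()].
#' @return invisibly, the vector of rates CSV paths.
#' @export
extract_rates <- function(indir, outdir, config = default_config(),
                          windows = config$window_lengths,
                          sensors = c("acc", "gyr")) {
  dirs <- subject_dirs(indir)
  if (!length(dirs)) stop("no subject directories (subject_NN) under ", indir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_config(config)
  paths <- character(length(dirs))
  for (i in seq_along(dirs)) {
    d <- dirs[i]
    subj <- list(recording = read_recording(file.path(d, "imu.csv")),
                 reference = read_reference(file.path(d, "ecg.csv"),
                                            file.path(d, "resp.csv")),
                 protocol = read_protocol(file.path(d, "protocol.yaml")))
    id <- basename(d)
    tbl <- process_subject(subj, config, windows, sensors, subject_id = id)
    paths[i] <- file.path(outdir, paste0("rates_", id, ".csv"))
    utils::write.csv(tbl, paths[i], row.names = FALSE)
    vitals_log("INFO", "extracted ", paths[i])
  }
  invisible(paths)
}

#' Evaluate agreement from extracted rate tables
#'
#' @param indir directory holding `rates_*.csv` files from [extract_rates()].
#' @param outdir output directory for `agreement_report.csv`.
#' @param loa_multiplier LOA half-width in SD units.
#' @return the `agreement_report`, invisibly.
#' @export
evaluate_rates <- function(indir, outdir, loa_multiplier = 1.96) {
  files <- sort(list.files(indir, pattern = "^rates_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no input: no rates_*.csv files under ", indir)
  rates <- do.call(rbind, c(lapply(files, utils::read.csv),
                            make.row.names = FALSE))
  report <- build_report(rates, loa_multiplier = loa_multiplier)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_agreement_report(report, file.path(outdir, "agreement_report.csv"))
  vitals_log("INFO", "wrote ", file.path(outdir, "agreement_report.csv"))
  invisible(report)
}

#' Replicate the full simulated study end to end
#'
#' Simulation, rate extraction and agreement evaluation in sequence, under
#' one seed. Deterministic: identical `(arguments, seed)` produce
#' byte-identical CSV outputs. A run manifest (seed, cohort size, package
#' version and the full configuration) is written alongside the report.
#'
#' @param outdir run directory; recordings go to `recordings/`, rate tables
#'   to `rates/`, the report and manifest to the top level.
#' @inheritParams simulate_cohort
#' @param config a [default_config()].
#' @param windows,sensors as in [process_segment()].
#' @return the `agreement_report`, invisibly.
#' @export
replicate_study <- function(outdir, n_subjects = 11, seed = 1,
                            config = default_config(),
                            postures = c("sitting", "standing", "lying"),
                            segment_s = 120, apnea_s = 20,
                            windows = config$window_lengths,
                            sensors = c("acc", "gyr")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simulate_cohort(file.path(outdir, "recordings"), n_subjects, seed,
                  postures, segment_s, apnea_s)
  extract_rates(file.path(outdir, "recordings"), file.path(outdir, "rates"),
                config, windows, sensors)
  report <- evaluate_rates(file.path(outdir, "rates"), outdir,
                           loa_multiplier = config$loa_multiplier)
  yaml::write_yaml(list(seed = seed, n_subjects = n_subjects,
                        postures = postures, segment_s = segment_s,
                        apnea_s = apnea_s, windows = windows,
                        sensors = sensors,
                        package_version = as.character(utils::packageVersion("imuvitals")),
                        config = unclass(config)),
                   file.path(outdir, "manifest.yaml"), precision = 15L)
  invisible(report)
}
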