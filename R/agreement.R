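# Agreement statistics: Bland-Altman mean of differences (MOD) with 1.96-SD
# limits of agreement (LOA), and mean absolute error (MAE), between the
# mechanically derived rate series and the reference-derived ones. All
# sliding windows are pooled within a group (sensor x posture x window
# length), as in the source study design; invalid (apnea-flagged) windows
# are excluded pairwise.

#' Pair a mechanical and a reference rate series
#'
#' Both series must come from the same window grid (same length and step, so
#' identical window centers); pairs where either estimate is flagged invalid
#' are dropped from both sides.
#'
#' @param est,ref `rate_series` objects (see [extract_rate_series()]).
#' @return `data.frame` with columns `window_center_s`, `est`, `ref`;
#'   attribute `n_excluded` counts the dropped pairs.
#' @export
pair_rate_series <- function(est, ref) {
  if (nrow(est) != nrow(ref) ||
      any(abs(est$window_center_s - ref$window_center_s) > 1e-9))
    stop("rate series have different window centers; use the same window length and step")
  keep <- est$valid & ref$valid
  structure(
    data.frame(window_center_s = est$window_center_s[keep],
               est = est$rate[keep], ref = ref$rate[keep]),
    n_excluded = sum(!keep))
}

as_pairs <- function(est, ref) {
  if (is.data.frame(est) && all(c("est", "ref") %in% names(est))) {
    if (!missing(ref) && !is.null(ref)) stop("supply either a paired table or two vectors")
    est
  } else {
    if (length(est) != length(ref)) stop("est and ref must have equal length")
    keep <- !is.na(est) & !is.na(ref)
    data.frame(est = est[keep], ref = ref[keep])
  }
}

#' Bland-Altman agreement statistics
#'
#' Differences are `est - ref`; MOD is their mean and the limits of agreement
#' are `MOD +/- multiplier * SD` with the sample (n-1) standard deviation and
#' a 1.96 multiplier (the conventional 95% interval).
#'
#' @param est paired table from [pair_rate_series()], or a numeric vector.
#' @param ref numeric vector when `est` is one.
#' @param loa_multiplier LOA half-width in SD units.
#' @return list with `mod`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(est, ref = NULL, loa_multiplier = 1.96) {
  p <- as_pairs(est, ref)
  if (nrow(p) < 2) stop("Bland-Altman needs at least 2 valid pairs")
  d <- p$est - p$ref
  mod <- mean(d)
  s <- stats::sd(d)
  list(mod = mod, loa_lower = mod - loa_multiplier * s,
       loa_upper = mod + loa_multiplier * s, sd_diff = s, n = nrow(p))
}

#' Mean absolute error between paired estimates
#'
#' @inheritParams bland_altman
#' @return mean of `|est - ref|`.
#' @export
mae <- function(est, ref = NULL) {
  p <- as_pairs(est, ref)
  if (nrow(p) < 1) stop("MAE needs at least 1 valid pair")
  mean(abs(p$est - p$ref))
}

#' Build the grouped agreement report
#'
#' Takes the long estimates table produced by [process_subject()] /
#' [extract_rates()] (columns `subject`, `posture`, `vital`, `source`,
#' `window_s`, `center_s`, `rate`, `valid`, with `source` one of `acc`,
#' `gyr`, `ref`) and computes, for every vital x sensor x posture x window
#' length, the pooled-over-subjects MOD, LOA and MAE against the reference,
#' plus a per-subject MAE breakdown. Rows are emitted in a deterministic
#' order.
#'
#' @param rates long estimates `data.frame`.
#' @param loa_multiplier LOA half-width in SD units.
#' @return `data.frame` of class `agreement_report` with columns `vital`,
#'   `sensor`, `posture`, `window_s`, `subject` (`"all"` for pooled rows),
#'   `mod`, `loa_lower`, `loa_upper`, `mae`, `n_pairs`, `n_excluded`.
#' @export
build_report <- function(rates, loa_multiplier = 1.96) {
  need <- c("subject", "posture", "vital", "source", "window_s", "center_s",
            "rate", "valid")
  if (!all(need %in% names(rates)))
    stop("rates table missing column(s): ",
         paste(setdiff(need, names(rates)), collapse = ", "))
  sensors <- sort(setdiff(unique(rates$source), "ref"))
  rows <- list()
  for (vital in sort(unique(rates$vital))) {
    for (sensor in sensors) {
      for (posture in unique(rates$posture)) {
        for (L in sort(unique(rates$window_s))) {
          sub_rows <- list()
          for (subj in sort(unique(rates$subject))) {
            sel <- rates$vital == vital & rates$posture == posture &
              rates$window_s == L & rates$subject == subj
            e <- rates[sel & rates$source == sensor, ]
            r <- rates[sel & rates$source == "ref", ]
            if (!nrow(e) || !nrow(r)) next
            e <- e[order(e$center_s), ]; r <- r[order(r$center_s), ]
            if (nrow(e) != nrow(r) || any(abs(e$center_s - r$center_s) > 1e-9))
              stop("mechanical and reference series are not aligned for ",
                   vital, "/", sensor, "/", posture, "/", L, "s")
            keep <- e$valid & r$valid
            sub_rows[[subj]] <- list(
              pairs = data.frame(est = e$rate[keep], ref = r$rate[keep]),
              n_excluded = sum(!keep), subject = subj)
          }
          if (!length(sub_rows)) next
          pooled <- do.call(rbind, lapply(sub_rows, `[[`, "pairs"))
          ba <- bland_altman(pooled, loa_multiplier = loa_multiplier)
          rows[[length(rows) + 1L]] <- data.frame(
            vital = vital, sensor = sensor, posture = posture, window_s = L,
            subject = "all", mod = ba$mod, loa_lower = ba$loa_lower,
            loa_upper = ba$loa_upper, mae = mae(pooled), n_pairs = ba$n,
            n_excluded = sum(vapply(sub_rows, `[[`, 0, "n_excluded")))
          for (sr in sub_rows) {
            if (nrow(sr$pairs) < 2) next
            ba_s <- bland_altman(sr$pairs, loa_multiplier = loa_multiplier)
            rows[[length(rows) + 1L]] <- data.frame(
              vital = vital, sensor = sensor, posture = posture, window_s = L,
              subject = sr$subject, mod = ba_s$mod, loa_lower = ba_s$loa_lower,
              loa_upper = ba_s$loa_upper, mae = mae(sr$pairs),
              n_pairs = ba_s$n, n_excluded = sr$n_excluded)
          }
        }
      }
    }
  }
  if (!length(rows)) stop("no overlapping mechanical/reference estimates to report")
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("agreement_report", "data.frame"))
}

#' Write an agreement report as a tidy CSV
#'
#' Long format: `metric, sensor, posture, window_s, subject, value, n`, where
#' `metric` combines the vital and the statistic (e.g. `hr_mod`, `rr_mae`).
#'
#' @param report an `agreement_report`.
#' @param path CSV file path.
#' @export
write_agreement_report <- function(report, path) {
  long <- list()
  for (stat in c("mod", "loa_lower", "loa_upper", "mae")) {
    long[[stat]] <- data.frame(
      metric = paste0(report$vital, "_", stat),
      sensor = report$sensor, posture = report$posture,
      window_s = report$window_s, subject = report$subject,
      value = report[[stat]], n = report$n_pairs)
  }
  long <- do.call(rbind, c(long, make.row.names = FALSE))
  long <- long[order(long$metric, long$sensor, long$posture,
                     long$window_s, long$subject), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
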