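#' Read and write the recording CSV dialect
#'
#' The raw-signal dialect is a plain CSV with numeric columns `time_s`,
#' `ax_g`, `ay_g`, `az_g` (seconds from study origin; acceleration in g),
#' sorted by time. Non-wear periods are absent rows, never NA. `read_recording()`
#' rejects malformed files with row-numbered diagnostics.
#'
#' @param path File path.
#' @param patient_id Identifier; defaults to the file stem.
#' @param sample_rate_hz Nominal rate (default 20 Hz).
#' @param study_span_h Hours enrolled; defaults to data span rounded up.
#' @return `read_recording()` returns a `gw_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, patient_id = NULL, sample_rate_hz = 20,
                           study_span_h = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), ax_g = readr::col_double(),
    ay_g = readr::col_double(), az_g = readr::col_double()),
    progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("empty recording file: %s", path))
  req <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(req %in% names(df))) {
    abort(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")))
  }
  bad <- which(!complete.cases(df[req]))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed (non-numeric or missing) value at data row %d",
                  path, bad[1]))
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono) > 0) {
    abort(sprintf("%s: time_s not strictly increasing at data row %d",
                  path, nonmono[1] + 1L))
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  as_recording(df, patient_id = patient_id, sample_rate_hz = sample_rate_hz,
               study_span_h = study_span_h)
}

#' @rdname read_recording
#' @param rec A `gw_recording`.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(as_tibble(rec)[c("time_s", "ax_g", "ay_g", "az_g")], path,
                   progress = FALSE)
  invisible(path)
}

#' Covered (wear) intervals of a recording
#'
#' Each sample covers one nominal sampling period `[t, t + 1/rate)`;
#' consecutive samples closer than `max_gap_factor` periods are bridged into
#' one covered interval; anything wider is a wear gap. This makes "hours with
#' sensor data" an explicit, reproducible union of half-open intervals.
#'
#' @param rec A `gw_recording`.
#' @param max_gap_factor Gap threshold in units of the nominal period
#'   (default 2: spacing up to twice the period still counts as covered).
#' @return Tibble with columns `start_s`, `end_s` of disjoint covered
#'   intervals, sorted.
#' @export
covered_intervals <- function(rec, max_gap_factor = 2) {
  fs <- sample_rate(rec)
  period <- 1 / fs
  t <- rec$time_s
  if (length(t) == 0) {
    return(tibble(start_s = numeric(), end_s = numeric()))
  }
  gap_after <- c(diff(t) > max_gap_factor * period, TRUE)
  run_end_idx <- which(gap_after)
  run_start_idx <- c(1L, head(run_end_idx, -1) + 1L)
  tibble(start_s = t[run_start_idx], end_s = t[run_end_idx] + period)
}

#' Total covered time in seconds
#' @inheritParams covered_intervals
#' @return Scalar seconds of wear time.
#' @export
covered_time_s <- function(rec, max_gap_factor = 2) {
  ci <- covered_intervals(rec, max_gap_factor)
  sum(ci$end_s - ci$start_s)
}

#' Monitoring ratio: hours with sensor data over hours enrolled
#'
#' The ratio of summed covered time to the study span, clamped to `[0, 1]`.
#' A patient wearing the device for 1,859 h of a 15-week (2,520 h) study has
#' a monitoring ratio of 0.738.
#'
#' @param rec A `gw_recording`.
#' @param study_hours Hours enrolled; defaults to the recording's
#'   `study_span_h` attribute.
#' @return Ratio in `[0, 1]`.
#' @export
monitoring_ratio <- function(rec, study_hours = NULL) {
  if (is.null(study_hours)) study_hours <- study_span_h(rec)
  stopifnot_scalar_number(study_hours, "study_hours")
  if (study_hours <= 0) abort("study span must be positive")
  min(1, max(0, covered_time_s(rec) / 3600 / study_hours))
}

#' Segment a recording into study-origin-relative days
#'
#' Days are half-open 24-h blocks `[d*86400, (d+1)*86400)` counted from the
#' study origin; a sample exactly on a boundary belongs to the later day.
#' Per-day wear is the covered time intersected with the day, so summed
#' `wear_h` equals total covered time exactly.
#'
#' @param rec A `gw_recording`.
#' @param n_days Number of days to report; defaults to the study span.
#' @return Tibble `date_index` (0-based), `start_s`, `end_s`, `wear_h`,
#'   `n_samples`.
#' @export
segment_days <- function(rec, n_days = NULL) {
  if (is.null(n_days)) {
    span_s <- study_span_h(rec) * 3600
    if (nrow(rec) > 0) span_s <- max(span_s, max(rec$time_s) + 1 / sample_rate(rec))
    n_days <- max(1L, ceiling(span_s / SECONDS_PER_DAY))
  }
  ci <- covered_intervals(rec)
  days <- tibble(
    date_index = seq_len(n_days) - 1L,
    start_s = (seq_len(n_days) - 1L) * SECONDS_PER_DAY,
    end_s = seq_len(n_days) * SECONDS_PER_DAY
  )
  days$wear_h <- purrr::map2_dbl(days$start_s, days$end_s, function(s, e) {
    sum(pmax(0, pmin(ci$end_s, e) - pmax(ci$start_s, s))) / 3600
  })
  if (nrow(rec) > 0) {
    cnt <- table(factor(floor(rec$time_s / SECONDS_PER_DAY),
                        levels = days$date_index))
    days$n_samples <- as.integer(cnt)
  } else {
    days$n_samples <- 0L
  }
  days
}

#' Resample a recording to a uniform rate by linear interpolation
#'
#' Interpolation happens only *within* covered intervals; no data are
#' fabricated across wear gaps.
#'
#' @param rec A `gw_recording`.
#' @param rate_hz Target rate (default the recording's nominal rate).
#' @return A new `gw_recording` on a uniform `1/rate_hz` grid.
#' @export
resample_recording <- function(rec, rate_hz = NULL) {
  if (is.null(rate_hz)) rate_hz <- sample_rate(rec)
  ci <- covered_intervals(rec)
  out <- purrr::pmap(ci, function(start_s, end_s) {
    idx <- rec$time_s >= start_s & rec$time_s < end_s
    tt <- rec$time_s[idx]
    if (length(tt) < 2) return(NULL)
    grid <- seq(ceiling(tt[1] * rate_hz) / rate_hz, tt[length(tt)], by = 1 / rate_hz)
    if (length(grid) == 0) return(NULL)
    tibble(
      time_s = grid,
      ax_g = approx(tt, rec$ax_g[idx], grid)$y,
      ay_g = approx(tt, rec$ay_g[idx], grid)$y,
      az_g = approx(tt, rec$az_g[idx], grid)$y
    )
  })
  as_recording(dplyr::bind_rows(out), patient_id = patient_id(rec),
               sample_rate_hz = rate_hz, study_span_h = study_span_h(rec))
}
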