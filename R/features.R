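#' Activity-time ratio
#'
#' Total time labelled with a gait-involving (ambulatory) activity divided by
#' the total monitoring time. The denominator is *covered* time, so windows
#' the classifier could not label still count toward monitoring.
#'
#' @param sample_labels Per-sample label tibble (`time_s`, `binary`) aligned
#'   to the recording.
#' @param monitoring_time_s Total covered time in seconds, e.g.
#'   [covered_time_s()].
#' @param sample_rate_hz Nominal rate used to convert sample counts to time.
#' @return Ratio in `[0, 1]`.
#' @export
activity_time_ratio <- function(sample_labels, monitoring_time_s,
                                sample_rate_hz = 20) {
  stopifnot_scalar_number(monitoring_time_s, "monitoring_time_s")
  if (monitoring_time_s <= 0) abort("monitoring time must be positive")
  amb_s <- sum(sample_labels$binary == "ambulatory", na.rm = TRUE) / sample_rate_hz
  min(1, amb_s / monitoring_time_s)
}

#' Median daily gesture count
#'
#' The median of per-day gesture counts over qualifying days (days with at
#' least `min_wear_h` hours of wear). An even number of qualifying days gives
#' the mean of the two middle counts. Days with too little wear are excluded
#' rather than counted as zeros; with no qualifying day the feature is
#' missing (`NA`), not zero.
#'
#' @param daily Tibble with `gesture_count` and `wear_h` per day, e.g. from
#'   [daily_gesture_counts()].
#' @param min_wear_h Minimum wear hours for a day to qualify (default 8).
#' @return Median count, or `NA` if no day qualifies.
#' @export
median_daily_gesture_count <- function(daily, min_wear_h = 8) {
  qual <- daily$gesture_count[daily$wear_h >= min_wear_h]
  if (length(qual) == 0) return(NA_real_)
  median(qual)
}

#' Aggregate gesture power
#'
#' Per qualifying day, the median of per-event powers; then the median of
#' those daily medians. Missing (`NA`) when no qualifying day has an event.
#'
#' @param events Event tibble (`start_s`, `power_g2`).
#' @param day_segments Day table from [segment_days()] (needs `date_index`,
#'   `wear_h`).
#' @param min_wear_h Minimum wear hours for a day to qualify (default 8).
#' @param agg Aggregation across days and events: `"median"` (default) or
#'   `"mean"`.
#' @return Aggregate power in g^2, or `NA`.
#' @export
aggregate_gesture_power <- function(events, day_segments, min_wear_h = 8,
                                    agg = c("median", "mean")) {
  agg <- match.arg(agg)
  f <- if (agg == "median") median else mean
  if (nrow(events) == 0) return(NA_real_)
  ev <- tibble(date_index = floor(events$start_s / SECONDS_PER_DAY),
               power_g2 = events$power_g2) %>%
    dplyr::inner_join(day_segments[c("date_index", "wear_h")], by = "date_index") %>%
    dplyr::filter(.data$wear_h >= min_wear_h)
  if (nrow(ev) == 0) return(NA_real_)
  daily <- ev %>%
    dplyr::group_by(.data$date_index) %>%
    dplyr::summarise(p = f(.data$power_g2), .groups = "drop")
  f(daily$p)
}

#' Per-patient digital outcome features
#'
#' Assembles the four sensor-derived outcome measures for one patient:
#' activity-time ratio, median daily gesture count, aggregate gesture power
#' and monitoring ratio, plus the number of qualifying days used.
#'
#' @param rec A `gw_recording`.
#' @param sample_labels Per-sample activity labels aligned to `rec`.
#' @param events Detected gesture events for `rec`.
#' @param min_wear_h Valid-day rule (default 8 h of wear).
#' @param study_hours Hours enrolled (defaults to the recording attribute).
#' @return One-row tibble: `patient_id`, `activity_time_ratio`,
#'   `median_daily_gesture_count`, `gesture_power_agg`, `monitoring_ratio`,
#'   `n_days_used`.
#' @export
patient_features <- function(rec, sample_labels, events, min_wear_h = 8,
                             study_hours = NULL) {
  segs <- segment_days(rec)
  daily <- daily_gesture_counts(events, segs)
  tibble(
    patient_id = patient_id(rec),
    activity_time_ratio = activity_time_ratio(sample_labels,
                                              covered_time_s(rec),
                                              sample_rate(rec)),
    median_daily_gesture_count = median_daily_gesture_count(daily, min_wear_h),
    gesture_power_agg = aggregate_gesture_power(events, segs, min_wear_h),
    monitoring_ratio = monitoring_ratio(rec, study_hours),
    n_days_used = sum(segs$wear_h >= min_wear_h)
  )
}
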