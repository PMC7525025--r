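#' Gesture-detector configuration
#'
#' The detector flags stationary time whose 1-s moving-window SD of the
#' acceleration magnitude exceeds 0.01 g. The threshold comes from the
#' observation that below 0.01 g moving SD a wrist is idle with ~99%
#' probability; eligible windows separated by less than `max_gap_s` are merged
#' into one event.
#'
#' @param sd_threshold_g Moving-SD threshold in g (default 0.01); comparison
#'   is strict (`>`).
#' @param window_s Moving-window length in seconds (default 1.0).
#' @param max_gap_s Maximal separation between eligible windows merged into
#'   one event, seconds; the rule is strict (`<`), so windows exactly 1 s
#'   apart start a new event (default 1.0). Separation is measured between
#'   window start times.
#' @param stride_samples Window stride in samples (default 1: per-sample
#'   sliding).
#' @return List of class `gw_gesture_config`.
#' @export
gesture_config <- function(sd_threshold_g = 0.01, window_s = 1.0,
                           max_gap_s = 1.0, stride_samples = 1L) {
  stopifnot_scalar_number(sd_threshold_g, "sd_threshold_g", positive = TRUE)
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  stopifnot_scalar_number(max_gap_s, "max_gap_s", positive = TRUE)
  structure(list(sd_threshold_g = sd_threshold_g, window_s = window_s,
                 max_gap_s = max_gap_s,
                 stride_samples = as.integer(stride_samples)),
            class = "gw_gesture_config")
}

#' Euclidean magnitude of the acceleration signal
#'
#' @param rec A `gw_recording` (or data frame with `time_s`, `ax_g`, `ay_g`,
#'   `az_g`).
#' @return Tibble `time_s`, `m_g` with the per-sample magnitude
#'   \eqn{\sqrt{a_x^2 + a_y^2 + a_z^2}} in g. Rotation of the device about
#'   any axis leaves the magnitude unchanged.
#' @examples
#' accel_magnitude(tibble::tibble(time_s = 0, ax_g = 0.6, ay_g = 0.8, az_g = 0))
#' @export
accel_magnitude <- function(rec) {
  tibble(time_s = rec$time_s,
         m_g = sqrt(rec$ax_g^2 + rec$ay_g^2 + rec$az_g^2))
}

#' Moving-window SD of a magnitude series
#'
#' Computes the population SD (denominator n) of the magnitude over a sliding
#' window of `window_s` seconds (`window_s * rate` samples), with per-sample
#' stride, separately within each covered span; windows that would cross a
#' wear gap are skipped. The streaming implementation centres each span
#' before accumulating running sums, so it matches a direct per-window
#' recomputation to well below 1e-9 g.
#'
#' @param ms Magnitude tibble from [accel_magnitude()] (columns `time_s`,
#'   `m_g`).
#' @param config A [gesture_config()].
#' @param sample_rate_hz Nominal rate of the source recording.
#' @return Tibble `start_s`, `end_s`, `sd_g`, `i_start` (index of the
#'   window's first sample in `ms`), one row per eligible window position.
#' @export
moving_sd <- function(ms, config = gesture_config(), sample_rate_hz = 20) {
  w <- as.integer(round(config$window_s * sample_rate_hz))
  if (w < 2) abort("window must span at least 2 samples")
  t <- ms$time_s
  x <- ms$m_g
  n <- length(t)
  if (n == 0) {
    return(tibble(start_s = numeric(), end_s = numeric(), sd_g = numeric(),
                  i_start = integer()))
  }
  period <- 1 / sample_rate_hz
  run_id <- cumsum(c(0, diff(t) > 2 * period))
  stride <- config$stride_samples
  out <- lapply(split(seq_len(n), run_id), function(idx) {
    m <- length(idx)
    if (m < w) return(NULL)
    xs <- x[idx]
    x0 <- xs - mean(xs)                     # centring keeps the sums small
    s1 <- c(0, cumsum(x0))
    s2 <- c(0, cumsum(x0 * x0))
    k <- m - w + 1L
    pos <- seq(1L, k, by = stride)
    S1 <- s1[pos + w] - s1[pos]
    S2 <- s2[pos + w] - s2[pos]
    v <- pmax(0, S2 / w - (S1 / w)^2)
    tibble(start_s = t[idx[pos]], end_s = t[idx[pos]] + config$window_s,
           sd_g = sqrt(v), i_start = idx[pos])
  })
  dplyr::bind_rows(out)
}

#' Detect gesture events
#'
#' A gesture event is a maximal run of *eligible* 1-s windows: windows whose
#' samples are all labelled stationary and whose moving SD of the magnitude
#' strictly exceeds the 0.01 g threshold. Eligible windows whose start times
#' differ by less than `max_gap_s` are merged into one event (the merge never
#' bridges a non-stationary window or a wear gap). The reported event spans
#' the eligible windows' centres — from the first eligible window's centre to
#' the last one's (half-open) — since a moving-window statistic is naturally
#' indexed at its centre; this keeps boundaries within half a window of the
#' underlying burst even for sub-second events. Ambulatory time never
#' produces events, however violent the signal.
#'
#' @param rec A `gw_recording`.
#' @param labels Per-sample labels aligned to `rec`: a tibble with `time_s`
#'   and a `binary` column (`"ambulatory"`/`"stationary"`, NA = unclassified),
#'   e.g. from [labels_to_samples()] or [schedule_sample_labels()].
#' @param config A [gesture_config()].
#' @return Tibble of class `gw_events`: `start_s`, `end_s`, `n_samples`,
#'   `power_g2` (per-event \eqn{\sum_t (m_t - \bar m)^2}), sorted,
#'   non-overlapping.
#' @export
detect_gestures <- function(rec, labels, config = gesture_config()) {
  if (nrow(labels) != nrow(rec) ||
      (nrow(rec) > 0 && max(abs(labels$time_s - rec$time_s)) > 1e-9)) {
    abort("`labels` must be per-sample and aligned to the recording")
  }
  fs <- sample_rate(rec)
  ms <- accel_magnitude(rec)
  wins <- moving_sd(ms, config, sample_rate_hz = fs)
  empty <- tibble(start_s = numeric(), end_s = numeric(),
                  n_samples = integer(), power_g2 = numeric())
  class(empty) <- c("gw_events", class(empty))
  if (nrow(wins) == 0) return(empty)

  w <- as.integer(round(config$window_s * fs))
  stat <- !is.na(labels$binary) & labels$binary == "stationary"
  cs <- cumsum(c(0L, as.integer(stat)))
  all_stat <- (cs[wins$i_start + w] - cs[wins$i_start]) == w

  cand <- wins[all_stat, ]                 # windows fully inside stationary time
  if (nrow(cand) == 0) return(empty)
  eligible <- cand$sd_g > config$sd_threshold_g

  # group eligible windows: a new event starts when the start-time gap to the
  # previous eligible window is >= max_gap_s (strict merge rule), or when a
  # non-stationary window / coverage break lies in between (candidate run id)
  cand_run <- cumsum(c(0, diff(cand$i_start) > config$stride_samples))
  el <- cand[eligible, ]
  if (nrow(el) == 0) return(empty)
  el_run <- cand_run[eligible]
  new_event <- c(TRUE, diff(el$start_s) >= config$max_gap_s |
                         diff(el_run) != 0)
  ev_id <- cumsum(new_event)

  # boundaries at the eligible windows' centres: a moving-window statistic is
  # indexed at its centre, and the half-window trim keeps short events tight
  half <- w %/% 2L
  m <- ms$m_g
  events <- el %>%
    dplyr::mutate(ev = ev_id) %>%
    dplyr::group_by(.data$ev) %>%
    dplyr::summarise(first_s = min(.data$start_s),
                     last_s = max(.data$start_s),
                     i_lo = min(.data$i_start) + half,
                     i_hi = max(.data$i_start) + half,
                     .groups = "drop") %>%
    dplyr::mutate(start_s = .data$first_s + config$window_s / 2,
                  end_s = .data$last_s + config$window_s / 2 + 1 / fs) %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      n_samples = .data$i_hi - .data$i_lo + 1L,
      power_g2 = {
        mm <- m[.data$i_lo:.data$i_hi]
        sum((mm - mean(mm))^2)
      }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$start_s) %>%
    dplyr::select("start_s", "end_s", "n_samples", "power_g2")
  class(events) <- c("gw_events", class(events))
  events
}

#' Gesture power of a set of magnitude samples
#'
#' \eqn{\sum_t (m_t - \bar m)^2} over the samples of one event, where
#' \eqn{m_t} is the acceleration magnitude and \eqn{\bar m} its mean across
#' the event; units g^2. Equals n times the population variance.
#'
#' @param m_g Numeric vector of magnitudes (g) for one event; length >= 2.
#' @return Scalar power in g^2.
#' @examples
#' gesture_power(c(0.9, 1.1)) # 0.02
#' @export
gesture_power <- function(m_g) {
  if (length(m_g) < 2) abort("a gesture event needs at least 2 samples")
  sum((m_g - mean(m_g))^2)
}

#' Daily gesture counts
#'
#' Events are assigned to the study-origin-relative day containing their
#' start time.
#'
#' @param events Event tibble (`start_s`, ...), e.g. from
#'   [detect_gestures()].
#' @param day_segments Day table from [segment_days()].
#' @return `day_segments` with an added integer `gesture_count` column.
#' @export
daily_gesture_counts <- function(events, day_segments) {
  counts <- table(factor(floor(events$start_s / SECONDS_PER_DAY),
                         levels = day_segments$date_index))
  dplyr::mutate(day_segments, gesture_count = as.integer(counts))
}

#' Plot detected gesture events over the magnitude trace
#'
#' @param object A `gw_events` tibble.
#' @param rec Optional `gw_recording` to draw the magnitude behind the
#'   events.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_events
#' @export
autoplot.gw_events <- function(object, rec = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(rec)) {
    ms <- accel_magnitude(rec)
    p <- p + ggplot2::geom_line(data = ms,
      ggplot2::aes(x = .data$time_s, y = .data$m_g), linewidth = 0.2)
  }
  p +
    ggplot2::geom_rect(data = as_tibble(object),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.25) +
    ggplot2::labs(x = "time (s)", y = "|a| (g)",
                  title = sprintf("%d gesture events", nrow(object)))
}
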