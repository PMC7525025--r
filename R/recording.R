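#' Construct an accelerometer recording
#'
#' A recording is a tibble with columns `time_s`, `ax_g`, `ay_g`, `az_g`
#' (acceleration in units of g, time in seconds from the study origin) plus
#' attributes `patient_id`, `sample_rate_hz` (nominal, 20 Hz for the wrist
#' device emulated here) and `study_span_h` (hours enrolled). Non-wear time is
#' represented by *absent* samples, never by `NA` rows; any inter-sample
#' spacing larger than twice the nominal period is treated as a wear gap by
#' all downstream coverage computations.
#'
#' @param samples Data frame with numeric columns `time_s`, `ax_g`, `ay_g`,
#'   `az_g`. Times must be strictly increasing and free of missing values.
#' @param patient_id Identifier string.
#' @param sample_rate_hz Nominal sampling rate in Hz (default 20).
#' @param study_span_h Total hours enrolled; defaults to the span of the data
#'   rounded up to a whole hour.
#' @return A tibble of class `gw_recording`.
#' @examples
#' rec <- as_recording(tibble::tibble(
#'   time_s = seq(0, 9.95, by = 0.05),
#'   ax_g = 0, ay_g = 0, az_g = 1
#' ), patient_id = "p1")
#' sample_rate(rec)
#' @export
as_recording <- function(samples, patient_id = "unknown", sample_rate_hz = 20,
                         study_span_h = NULL) {
  required <- c("time_s", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("recording is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  samples <- as_tibble(samples)[required]
  if (nrow(samples) > 0) {
    if (anyNA(samples)) {
      abort("recording samples must not contain NA; gaps are absent rows")
    }
    bad <- which(diff(samples$time_s) <= 0)
    if (length(bad) > 0) {
      abort(sprintf("time_s must be strictly increasing; first violation at row %d",
                    bad[1] + 1L))
    }
  }
  if (is.null(study_span_h)) {
    study_span_h <- if (nrow(samples) == 0) 0 else
      ceiling(max(samples$time_s) / 3600)
  }
  structure(samples,
            class = c("gw_recording", class(samples)),
            patient_id = as.character(patient_id),
            sample_rate_hz = sample_rate_hz,
            study_span_h = study_span_h)
}

#' @rdname as_recording
#' @param rec A `gw_recording`.
#' @export
sample_rate <- function(rec) attr(rec, "sample_rate_hz") %||% 20

#' @rdname as_recording
#' @export
study_span_h <- function(rec) attr(rec, "study_span_h")

#' @rdname as_recording
#' @export
patient_id <- function(rec) attr(rec, "patient_id") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gw_recording <- function(x, ...) {
  cat(sprintf("<gw_recording> patient %s, %d samples @ %g Hz, study span %g h\n",
              patient_id(x), nrow(x), sample_rate(x), study_span_h(x)))
  NextMethod()
}

#' Plot a recording's tri-axial signal
#'
#' Downsamples long recordings for display and facets by axis.
#'
#' @param object A `gw_recording`.
#' @param max_points Maximum number of samples plotted per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gw_recording
#' @export
autoplot.gw_recording <- function(object, max_points = 20000, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  long <- tidyr::pivot_longer(df, c("ax_g", "ay_g", "az_g"),
                              names_to = "axis", values_to = "accel_g")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$accel_g)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)",
                  title = sprintf("Patient %s", patient_id(object)))
}
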