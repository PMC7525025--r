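#' Synthesize a tri-axial wrist signal from an activity schedule
#'
#' Generates 20 Hz (or `params$sample_rate_hz`) tri-axial acceleration for
#' every wear entry of a schedule. Stationary states produce a 1 g gravity
#' offset on the z axis plus Gaussian noise whose 1-s moving SD sits below
#' 0.01 g; ambulatory states add a gait oscillation (fundamental plus one
#' harmonic) whose moving SD is far above 0.01 g; hand work produces sustained
#' supra-threshold noise. Gesture bursts — short epochs of extra z-axis noise
#' with SD above 0.01 g — are planted as a Poisson process during quiet
#' stationary bouts (sitting, standing, lying down) and recorded as ground
#' truth with their realized per-event power.
#'
#' `non_wear` entries yield no samples at all: gaps are absent rows.
#'
#' @param schedule Schedule tibble from [simulate_schedule()].
#' @param params A [signal_params()] object.
#' @param seed Integer seed.
#' @param patient_id Identifier stored on the recording.
#' @return A list of class `gw_simulation` with elements
#'   \describe{
#'     \item{recording}{a [as_recording()] tibble,}
#'     \item{truth_events}{tibble `start_s`, `end_s`, `n_samples`,
#'       `power_g2` of planted gesture bursts (sample-aligned, half-open),}
#'     \item{schedule}{the input schedule (ground-truth labels).}
#'   }
#' @examples
#' sch <- tibble::tibble(state = "sitting", start_s = 0, end_s = 120)
#' sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 60), seed = 7)
#' nrow(sim$recording)
#' @export
simulate_recording <- function(schedule, params = signal_params(), seed = NULL,
                               patient_id = "sim") {
  validate_schedule(schedule)
  if (!inherits(params, "gw_signal_params")) {
    abort("`params` must be created with signal_params()")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  fs <- params$sample_rate_hz

  withr::with_seed(seed, {
    chunks <- purrr::pmap(schedule, function(state, start_s, end_s) {
      synth_entry(state, start_s, end_s, params)
    })
  })
  samples <- dplyr::bind_rows(purrr::map(chunks, "samples"))
  events <- dplyr::bind_rows(purrr::map(chunks, "events"))

  rec <- as_recording(samples, patient_id = patient_id, sample_rate_hz = fs,
                      study_span_h = max(schedule$end_s) / 3600)

  if (nrow(events) > 0) {
    m <- accel_magnitude(rec)
    events <- events %>%
      dplyr::rowwise() %>%
      dplyr::mutate(power_g2 = {
        mm <- m$m_g[m$time_s >= .data$start_s & m$time_s < .data$end_s]
        sum((mm - mean(mm))^2)
      }, n_samples = sum(m$time_s >= .data$start_s & m$time_s < .data$end_s)) %>%
      dplyr::ungroup() %>%
      dplyr::arrange(.data$start_s)
  } else {
    events <- tibble(start_s = numeric(), end_s = numeric(),
                     n_samples = integer(), power_g2 = numeric())
  }

  structure(list(recording = rec, truth_events = events, schedule = schedule),
            class = "gw_simulation")
}

synth_entry <- function(state, start_s, end_s, params) {
  fs <- params$sample_rate_hz
  n <- round((end_s - start_s) * fs)
  empty <- list(samples = NULL, events = NULL)
  if (state == NON_WEAR || n == 0) return(empty)
  t <- start_s + (seq_len(n) - 1) / fs

  if (state %in% AMBULATORY_STATES) {
    f <- params$gait_freq_hz[[state]]
    A <- params$gait_amp_g[[state]]
    phi <- runif(1, 0, 2 * pi)
    nz <- params$gait_noise_sd_g
    az <- params$gravity_g + A * sin(2 * pi * f * t + phi) +
      0.4 * A * sin(4 * pi * f * t + 2 * phi) + rnorm(n, 0, nz)
    ax <- 0.5 * A * sin(2 * pi * f * t + phi + 1.0) + rnorm(n, 0, nz)
    ay <- 0.3 * A * sin(2 * pi * f * t + phi + 2.1) + rnorm(n, 0, nz)
    return(list(samples = tibble(time_s = t, ax_g = ax, ay_g = ay, az_g = az),
                events = NULL))
  }

  noise_sd <- if (state == "hand_work") params$hand_work_sd_g else
    params$idle_noise_sd_g
  ax <- rnorm(n, 0, noise_sd)
  ay <- rnorm(n, 0, noise_sd)
  az <- params$gravity_g + rnorm(n, 0, noise_sd)
  events <- NULL

  # plant gesture bursts only in quiet stationary bouts
  if (state != "hand_work" && params$gesture_rate_per_h > 0) {
    dur_h <- (end_s - start_s) / 3600
    k <- rpois(1, params$gesture_rate_per_h * dur_h)
    if (k > 0) {
      durs <- runif(k, params$gesture_dur_s_range[1], params$gesture_dur_s_range[2])
      starts <- runif(k, start_s, pmax(start_s, end_s - durs))
      ord <- order(starts)
      starts <- starts[ord]; durs <- durs[ord]
      keep_start <- numeric(0); keep_end <- numeric(0)
      prev_end <- -Inf
      for (i in seq_len(k)) {
        gs <- starts[i]; ge <- min(gs + durs[i], end_s)
        if (gs >= prev_end + params$gesture_min_sep_s && ge - gs >= params$gesture_dur_s_range[1]) {
          keep_start <- c(keep_start, gs); keep_end <- c(keep_end, ge)
          prev_end <- ge
        }
      }
      if (length(keep_start) > 0) {
        ev <- purrr::map2(keep_start, keep_end, function(gs, ge) {
          idx <- which(t >= gs & t < ge)
          if (length(idx) < 2) return(NULL)
          az[idx] <<- az[idx] + rnorm(length(idx), 0, params$gesture_amp_sd_g)
          tibble(start_s = t[idx[1]], end_s = t[idx[length(idx)]] + 1 / fs)
        })
        events <- dplyr::bind_rows(ev)
      }
    }
  }

  list(samples = tibble(time_s = t, ax_g = ax, ay_g = ay, az_g = az),
       events = events)
}
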