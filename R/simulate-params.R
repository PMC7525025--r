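#' Signal-model parameters for synthetic recordings
#'
#' Defaults encode the regime the gesture detector assumes: stationary wrist
#' noise well below the 0.01 g moving-SD threshold, gesture bursts well above
#' it, and gait oscillation (fundamental plus one harmonic) far above it.
#' Gravity contributes a constant 1 g offset along the z axis so the
#' acceleration magnitude hovers near 1 g at rest.
#'
#' @param sample_rate_hz Sampling rate in Hz; the emulated wrist device
#'   records at 20 Hz.
#' @param gait_freq_hz Named vector of per-state fundamental frequencies (Hz)
#'   for the ambulatory states.
#' @param gait_amp_g Named vector of oscillation amplitudes (g) for the
#'   ambulatory states.
#' @param gait_noise_sd_g Additive noise SD (g) during ambulatory states.
#' @param idle_noise_sd_g Stationary baseline noise SD (g); must be < 0.01 so
#'   idle time sits below the detector threshold.
#' @param hand_work_sd_g Noise SD (g) during hand work (stationary but with
#'   sustained wrist movement; intentionally above threshold, mirroring the
#'   known contamination of gesture detection by instrumental hand activity).
#' @param gesture_rate_per_h Poisson rate of gesture bursts per stationary
#'   hour.
#' @param gesture_dur_s_range Length-2 numeric, uniform range of burst
#'   durations in seconds.
#' @param gesture_amp_sd_g Burst noise SD (g); must be > 0.01 so bursts are
#'   detectable in the 1-s moving SD.
#' @param gesture_min_sep_s Minimum separation in seconds between planted
#'   bursts within one stationary bout.
#' @param gravity_g Constant gravity offset in g.
#' @return A list of class `gw_signal_params`.
#' @examples
#' p <- signal_params(gesture_rate_per_h = 10)
#' p$idle_noise_sd_g
#' @export
signal_params <- function(sample_rate_hz = 20,
                          gait_freq_hz = c(walking = 1.8, climbing_stairs = 1.5,
                                           cycling = 1.1, jogging = 2.7),
                          gait_amp_g = c(walking = 0.22, climbing_stairs = 0.28,
                                         cycling = 0.16, jogging = 0.55),
                          gait_noise_sd_g = 0.03,
                          idle_noise_sd_g = 0.004,
                          hand_work_sd_g = 0.05,
                          gesture_rate_per_h = 6,
                          gesture_dur_s_range = c(0.5, 5),
                          gesture_amp_sd_g = 0.05,
                          gesture_min_sep_s = 3,
                          gravity_g = 1.0) {
  stopifnot_scalar_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  stopifnot_scalar_number(idle_noise_sd_g, "idle_noise_sd_g")
  stopifnot_scalar_number(gesture_amp_sd_g, "gesture_amp_sd_g", positive = TRUE)
  if (idle_noise_sd_g < 0) abort("idle_noise_sd_g must be >= 0")
  if (idle_noise_sd_g >= 0.01) {
    abort("idle_noise_sd_g must be < 0.01 g: stationary noise at or above the detector threshold violates the detectability premise")
  }
  if (gesture_amp_sd_g <= 0.01) {
    abort("gesture_amp_sd_g must be > 0.01 g for bursts to be detectable")
  }
  if (length(gesture_dur_s_range) != 2 || diff(gesture_dur_s_range) < 0 ||
      gesture_dur_s_range[1] <= 0) {
    abort("gesture_dur_s_range must be (min, max) with 0 < min <= max")
  }
  missing_states <- setdiff(AMBULATORY_STATES, names(gait_freq_hz))
  if (length(missing_states) > 0) {
    abort(paste0("gait_freq_hz must name every ambulatory state; missing: ",
                 paste(missing_states, collapse = ", ")))
  }
  structure(list(
    sample_rate_hz = sample_rate_hz,
    gait_freq_hz = gait_freq_hz,
    gait_amp_g = gait_amp_g,
    gait_noise_sd_g = gait_noise_sd_g,
    idle_noise_sd_g = idle_noise_sd_g,
    hand_work_sd_g = hand_work_sd_g,
    gesture_rate_per_h = gesture_rate_per_h,
    gesture_dur_s_range = gesture_dur_s_range,
    gesture_amp_sd_g = gesture_amp_sd_g,
    gesture_min_sep_s = gesture_min_sep_s,
    gravity_g = gravity_g
  ), class = "gw_signal_params")
}
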