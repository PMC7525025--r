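#' Simulate an annotated multi-subject training bank
#'
#' Emulates the structure of the two public annotated wrist-accelerometer
#' datasets used to train activity-recognition models: two sources, each with
#' several subjects performing a scripted protocol covering all eight
#' activity states. The sources differ systematically (gait cadence and
#' amplitude offsets) and each subject adds idiosyncratic multipliers, so
#' held-out-subject evaluation is a real generalization test. Protocol
#' recordings are scripted activity blocks, so no gesture bursts are planted.
#'
#' @param n_per_source Subjects per source (default 9, giving the 14/2/2
#'   train/validation/test split under [har_split()]).
#' @param minutes_per_subject Scripted protocol length per subject
#'   (default 10).
#' @param duration_s,stride_s Window length and stride passed to
#'   [slice_windows()].
#' @param seed Integer seed.
#' @return Labelled window-feature tibble (columns `subject_id`, `source`,
#'   `fine`, `binary`, features) with the `"feature_cols"` attribute set.
#' @export
simulate_har_subjects <- function(n_per_source = 9, minutes_per_subject = 10,
                                  duration_s = 5, stride_s = 5, seed = 1) {
  seeds <- derive_seeds(seed, 2 * n_per_source + 1)
  source_tweaks <- list(
    reiss_like = list(freq_mul = 1.0, amp_mul = 1.0),
    stisen_like = list(freq_mul = 0.88, amp_mul = 1.2)
  )
  subj_grid <- tidyr::expand_grid(source = names(source_tweaks),
                                  subj = seq_len(n_per_source))
  out <- purrr::pmap(cbind(subj_grid, s = seeds[seq_len(nrow(subj_grid))]),
                     function(source, subj, s) {
    tw <- source_tweaks[[source]]
    withr::with_seed(s, {
      freq_jit <- runif(1, 0.92, 1.08)
      amp_jit <- runif(1, 0.85, 1.2)
      params <- signal_params(
        gait_freq_hz = c(walking = 1.8, climbing_stairs = 1.5, cycling = 1.1,
                         jogging = 2.7) * tw$freq_mul * freq_jit,
        gait_amp_g = c(walking = 0.22, climbing_stairs = 0.28, cycling = 0.16,
                       jogging = 0.55) * tw$amp_mul * amp_jit,
        gesture_rate_per_h = 0
      )
      block_s <- round(minutes_per_subject * 60 / 16)
      states <- c(sample(ACTIVITY_STATES), sample(ACTIVITY_STATES))
      sched <- tibble(
        state = states,
        start_s = (seq_along(states) - 1) * block_s,
        end_s = seq_along(states) * block_s
      )
      sim <- simulate_recording(sched, params, seed = s + 1,
                                patient_id = sprintf("%s_s%02d", source, subj))
      labs <- schedule_sample_labels(sim$recording, sched)
      win <- slice_windows(sim$recording, duration_s, stride_s, labels = labs)
      feats <- window_features(sim$recording, win)
      fc <- attr(feats, "feature_cols")
      feats <- dplyr::mutate(feats,
                             subject_id = sprintf("%s_s%02d", source, subj),
                             source = source)
      attr(feats, "feature_cols") <- fc
      feats
    })
  })
  fc <- attr(out[[1]], "feature_cols")
  res <- dplyr::bind_rows(out)
  attr(res, "feature_cols") <- fc
  res
}
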