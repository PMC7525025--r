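#' Slice a recording into fixed-length analysis windows
#'
#' Windows are placed on a stride grid anchored at the study origin; a window
#' is kept when at least `min_coverage` of its nominal samples are present
#' (windows straddling wear gaps with less coverage are dropped). When
#' `labels` (per-sample fine labels, e.g. [schedule_sample_labels()]) are
#' supplied, each window carries the majority fine label of its samples.
#'
#' @param rec A `gw_recording`.
#' @param duration_s Window length in seconds (default 5).
#' @param stride_s Stride between window starts (default `duration_s`,
#'   i.e. non-overlapping).
#' @param labels Optional per-sample label tibble (`time_s`, `fine`).
#' @param min_coverage Minimum fraction of nominal samples present
#'   (default 0.8).
#' @return Tibble `start_s`, `end_s`, `i_lo`, `i_hi`, `n_samples`,
#'   `coverage`, and `fine`/`binary` when labels are given.
#' @export
slice_windows <- function(rec, duration_s = 5, stride_s = duration_s,
                          labels = NULL, min_coverage = 0.8) {
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(stride_s, "stride_s", positive = TRUE)
  fs <- sample_rate(rec)
  t <- rec$time_s
  empty <- tibble(start_s = numeric(), end_s = numeric(), i_lo = integer(),
                  i_hi = integer(), n_samples = integer(), coverage = numeric())
  if (length(t) == 0) return(empty)
  full_n <- duration_s * fs
  p0 <- floor(t[1] / stride_s) * stride_s
  starts <- seq(p0, max(t), by = stride_s)
  eps <- 1e-9
  i_lo <- findInterval(starts - eps, t) + 1L
  i_hi <- findInterval(starts + duration_s - eps, t)
  keep <- i_hi >= i_lo
  win <- tibble(start_s = starts[keep], end_s = starts[keep] + duration_s,
                i_lo = i_lo[keep], i_hi = i_hi[keep]) %>%
    dplyr::mutate(n_samples = .data$i_hi - .data$i_lo + 1L,
                  coverage = .data$n_samples / full_n) %>%
    dplyr::filter(.data$coverage >= min_coverage - eps)
  if (!is.null(labels)) {
    if (nrow(labels) != nrow(rec)) {
      abort("`labels` must have one row per sample")
    }
    win <- win %>%
      dplyr::rowwise() %>%
      dplyr::mutate(fine = majority_label(labels$fine[.data$i_lo:.data$i_hi])) %>%
      dplyr::ungroup() %>%
      dplyr::mutate(binary = binary_activity(.data$fine))
  }
  win
}

majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  tab <- table(x)
  names(tab)[which.max(tab)]
}

#' Per-sample fine labels from a ground-truth schedule
#'
#' @param rec A `gw_recording`.
#' @param schedule Schedule tibble (`state`, `start_s`, `end_s`).
#' @return Tibble `time_s`, `fine`, `binary` aligned to the recording's
#'   samples (`fine` is NA outside the schedule or in `non_wear`).
#' @export
schedule_sample_labels <- function(rec, schedule) {
  validate_schedule(schedule)
  idx <- findInterval(rec$time_s, schedule$start_s)
  fine <- rep(NA_character_, nrow(rec))
  ok <- idx >= 1
  ok[ok] <- rec$time_s[ok] < schedule$end_s[idx[ok]]
  fine[ok] <- schedule$state[idx[ok]]
  fine[fine == NON_WEAR] <- NA_character_
  tibble(time_s = rec$time_s, fine = fine, binary = binary_activity(fine))
}

#' Per-sample labels from window-level predictions
#'
#' Each sample receives the label of the window(s) covering it; when
#' overlapping windows disagree, the majority label wins and ties go to the
#' label of the earliest covering window.
#'
#' @param window_labels Tibble `start_s`, `end_s`, `fine` (windows sorted by
#'   start).
#' @param rec A `gw_recording`.
#' @return Tibble `time_s`, `fine`, `binary` aligned to the samples.
#' @export
labels_to_samples <- function(window_labels, rec) {
  t <- rec$time_s
  n <- length(t)
  wl <- dplyr::arrange(window_labels, .data$start_s)
  fine <- rep(NA_character_, n)
  if (nrow(wl) > 0 && n > 0) {
    no_overlap <- nrow(wl) == 1 ||
      all(wl$start_s[-1] >= wl$end_s[-nrow(wl)] - 1e-9)
    if (no_overlap) {
      idx <- findInterval(t, wl$start_s)
      ok <- idx >= 1
      ok[ok] <- t[ok] < wl$end_s[idx[ok]]
      fine[ok] <- wl$fine[idx[ok]]
    } else {
      labs <- unique(wl$fine)
      votes <- matrix(0L, n, length(labs))
      firstw <- matrix(Inf, n, length(labs))
      eps <- 1e-9
      for (i in seq_len(nrow(wl))) {
        lo <- findInterval(wl$start_s[i] - eps, t) + 1L
        hi <- findInterval(wl$end_s[i] - eps, t)
        if (lo > hi) next
        j <- match(wl$fine[i], labs)
        votes[lo:hi, j] <- votes[lo:hi, j] + 1L
        firstw[lo:hi, j] <- pmin(firstw[lo:hi, j], i)
      }
      covered <- rowSums(votes) > 0
      fine[covered] <- vapply(which(covered), function(s) {
        v <- votes[s, ]
        tied <- which(v == max(v))
        labs[tied[which.min(firstw[s, tied])]]
      }, character(1))
    }
  }
  tibble(time_s = t, fine = fine, binary = binary_activity(fine))
}

#' Handcrafted features for activity-recognition windows
#'
#' For each of the three axes and the magnitude: mean, SD (and its log),
#' dominant frequency in the 0.5-5 Hz gait band, and spectral power in that
#' band (and its log; movement intensity spans orders of magnitude, so the
#' log versions make the ambulatory/stationary boundary close to linear), and
#' the band's peak-concentration ratio (peak bin power over band power — near
#' 1 for periodic gait, small for aperiodic hand movement); plus the three
#' between-axis correlations. Deterministic; 31 features per window.
#'
#' @param rec A `gw_recording`.
#' @param windows Window tibble from [slice_windows()].
#' @param band Frequency band of interest in Hz (default 0.5-5, covering
#'   human gait cadence and its first harmonic).
#' @return `windows` with feature columns appended; the feature column names
#'   are stored in the `"feature_cols"` attribute.
#' @export
window_features <- function(rec, windows, band = c(0.5, 5)) {
  fs <- sample_rate(rec)
  k <- nrow(windows)
  feature_names <- c(
    paste0(rep(c("mean_", "sd_", "logsd_", "domfreq_", "bandpow_",
                 "logbandpow_", "peakratio_"), 4),
           rep(c("x", "y", "z", "m"), each = 7)),
    "cor_xy", "cor_xz", "cor_yz")
  fmat <- matrix(NA_real_, k, length(feature_names),
                 dimnames = list(NULL, feature_names))
  # batch windows of equal sample count so spectra go through one mvfft
  for (g in split(seq_len(k), windows$n_samples[seq_len(k)])) {
    n <- windows$n_samples[g[1]]
    idx <- vapply(g, function(i) windows$i_lo[i]:windows$i_hi[i], integer(n))
    sigs <- list(x = matrix(rec$ax_g[idx], n),
                 y = matrix(rec$ay_g[idx], n),
                 z = matrix(rec$az_g[idx], n))
    sigs$m <- sqrt(sigs$x^2 + sigs$y^2 + sigs$z^2)
    freq <- (seq_len(n) - 1) * fs / n
    in_band <- freq <= fs / 2 & freq >= band[1] & freq <= band[2]
    centred <- list()
    for (nm in names(sigs)) {
      S <- sigs[[nm]]
      mu <- colMeans(S)
      C <- sweep(S, 2, mu)
      centred[[nm]] <- C
      sdv <- sqrt(colSums(C^2) / max(1, n - 1))
      P <- Mod(stats::mvfft(C))^2
      bp <- 2 * colSums(P[in_band, , drop = FALSE]) / n^2
      dom <- rep(0, length(g))
      if (any(in_band)) {
        fb <- freq[in_band]
        dom_idx <- max.col(t(P[in_band, , drop = FALSE]), ties.method = "first")
        dom <- ifelse(bp < 1e-12, 0, fb[dom_idx])
      }
      Pb <- P[in_band, , drop = FALSE]
      tot <- colSums(Pb)
      peak <- apply(Pb, 2, max)
      pr <- ifelse(tot > 0, peak / tot, 0)
      fmat[g, paste0(c("mean_", "sd_", "logsd_", "domfreq_", "bandpow_",
                       "logbandpow_", "peakratio_"), nm)] <-
        cbind(mu, sdv, log10(sdv + 1e-6), dom, bp, log10(bp + 1e-9), pr)
    }
    wcor <- function(a, b) {
      den <- sqrt(colSums(a^2) * colSums(b^2))
      ifelse(den == 0, 0, colSums(a * b) / den)
    }
    fmat[g, c("cor_xy", "cor_xz", "cor_yz")] <- cbind(
      wcor(centred$x, centred$y), wcor(centred$x, centred$z),
      wcor(centred$y, centred$z))
  }
  out <- dplyr::bind_cols(windows, as_tibble(fmat))
  attr(out, "feature_cols") <- feature_names
  out
}
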