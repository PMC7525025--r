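# Fixture builders and independent oracles used across the suite.

# recording with constant (or supplied) axis values on a uniform 20 Hz grid
flat_recording <- function(duration_s, fs = 20, ax = 0, ay = 0, az = 1,
                           t0 = 0, ...) {
  t <- t0 + (seq_len(round(duration_s * fs)) - 1) / fs
  as_recording(tibble::tibble(time_s = t, ax_g = ax, ay_g = ay, az_g = az),
               sample_rate_hz = fs, ...)
}

# recording whose z axis carries deterministic alternating +/-amp bursts on a
# constant-gravity baseline; burst SD is exactly amp within a full window
burst_recording <- function(duration_s, bursts, fs = 20, ...) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  az <- rep(1, length(t))
  for (b in seq_len(nrow(bursts))) {
    idx <- which(t >= bursts$start_s[b] & t < bursts$end_s[b])
    az[idx] <- 1 + bursts$amp_g[b] * (-1)^(seq_along(idx) - 1)
  }
  as_recording(tibble::tibble(time_s = t, ax_g = 0, ay_g = 0, az_g = az),
               sample_rate_hz = fs, ...)
}

all_stationary_labels <- function(rec, state = "sitting") {
  tibble::tibble(time_s = rec$time_s, fine = state,
                 binary = binary_activity(state))
}

# population-SD oracle
brute_pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# union-of-intervals coverage oracle: every sample covers one period, and
# pairs closer than 2 periods are bridged
brute_covered_s <- function(t, fs = 20) {
  period <- 1 / fs
  iv <- cbind(t, t + period)
  bridge <- which(diff(t) <= 2 * period)
  if (length(bridge) > 0) {
    iv <- rbind(iv, cbind(t[bridge], t[bridge + 1]))
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0
  cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_hi) {
      cur_hi <- max(cur_hi, iv[i, 2])
    } else {
      total <- total + cur_hi - cur_lo
      cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2]
    }
  }
  as.numeric(total + cur_hi - cur_lo)
}

# exhaustive lexicographic permutation enumeration (independent of the
# package's insertion-based generator)
lex_permutations <- function(n) {
  rec <- function(remaining) {
    if (length(remaining) == 1) return(list(remaining))
    out <- list()
    for (i in seq_along(remaining)) {
      for (p in rec(remaining[-i])) {
        out[[length(out) + 1]] <- c(remaining[i], p)
      }
    }
    out
  }
  rec(seq_len(n))
}

# greedy IoU matching of detected vs truth events
match_events <- function(truth, detected, iou_min = 0.5) {
  if (nrow(truth) == 0 || nrow(detected) == 0) {
    return(list(matches = integer(0), recall = 0, precision = 0))
  }
  used <- rep(FALSE, nrow(detected))
  matches <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    inter <- pmax(0, pmin(truth$end_s[i], detected$end_s) -
                       pmax(truth$start_s[i], detected$start_s))
    uni <- (truth$end_s[i] - truth$start_s[i]) +
      (detected$end_s - detected$start_s) - inter
    iou <- ifelse(used, 0, inter / uni)
    j <- which.max(iou)
    if (iou[j] > iou_min) {
      matches[i] <- j
      used[j] <- TRUE
    }
  }
  list(matches = matches,
       recall = mean(!is.na(matches)),
       precision = sum(!is.na(matches)) / nrow(detected))
}

# random 3x3 rotation matrix (QR with positive diagonal)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))))
}

rotate_recording <- function(rec, R) {
  A <- as.matrix(tibble::as_tibble(rec)[c("ax_g", "ay_g", "az_g")]) %*% t(R)
  as_recording(tibble::tibble(time_s = rec$time_s, ax_g = A[, 1],
                              ay_g = A[, 2], az_g = A[, 3]),
               patient_id = patient_id(rec),
               sample_rate_hz = sample_rate(rec),
               study_span_h = study_span_h(rec))
}
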