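test_that("magnitude is the Euclidean norm and rotation-invariant", {
  expect_equal(accel_magnitude(tibble::tibble(
    time_s = 0, ax_g = 0.6, ay_g = 0.8, az_g = 0))$m_g, 1.0)
  rec <- flat_recording(10)
  expect_true(all(accel_magnitude(rec)$m_g == 1.0))

  sch <- tibble::tibble(state = "sitting", start_s = 0, end_s = 120)
  sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 60), seed = 2)
  m0 <- accel_magnitude(sim$recording)$m_g
  set.seed(99)
  for (k in 1:5) {
    R <- random_rotation()
    mr <- accel_magnitude(rotate_recording(sim$recording, R))$m_g
    expect_lt(max(abs(mr - m0)), 1e-12)
  }
})

test_that("moving SD handles closed forms and matches the brute-force oracle", {
  # constant series -> 0 everywhere
  sds <- moving_sd(accel_magnitude(flat_recording(10)))
  expect_true(all(sds$sd_g == 0))

  # alternating +/- a about the mean -> SD exactly a
  a <- 0.03
  rec <- burst_recording(10, tibble::tibble(start_s = 0, end_s = 10, amp_g = a))
  sds <- moving_sd(accel_magnitude(rec))
  expect_equal(max(abs(sds$sd_g - a)), 0, tolerance = 1e-12)

  # random series: streaming result equals direct per-window recomputation
  worst <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- sample(40:200, 1)
    ms <- tibble::tibble(time_s = (seq_len(n) - 1) / 20,
                         m_g = 1 + rnorm(n, 0, 0.3))
    w <- moving_sd(ms)
    brute <- vapply(w$i_start, function(i) brute_pop_sd(ms$m_g[i:(i + 19)]), 1.0)
    worst <- max(worst, max(abs(w$sd_g - brute)))
  }
  expect_lt(worst, 1e-9)

  # windows never cross wear gaps
  t <- c(seq(0, 1.95, by = 0.05), seq(10, 11.95, by = 0.05))
  ms <- tibble::tibble(time_s = t, m_g = 1)
  w <- moving_sd(ms)
  expect_true(all(w$start_s + 1 <= 2.0 + 1e-9 | w$start_s >= 10))
})

test_that("a planted burst yields one event with sub-second boundary error", {
  rec <- burst_recording(30, tibble::tibble(start_s = 10, end_s = 13, amp_g = 0.05))
  ev <- detect_gestures(rec, all_stationary_labels(rec))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start_s - 10), 1)
  expect_lt(abs(ev$end_s - 13), 1)
  expect_gte(ev$start_s, 9)
  expect_lte(ev$end_s, 14)
})

test_that("sub-second gaps merge events and >= 1 s start gaps split them", {
  # bursts with amp 0.02 g: a window needs >= 0.3 s of burst to be eligible
  two <- function(gap) {
    burst_recording(30, tibble::tibble(start_s = c(10, 13 + gap),
                                       end_s = c(13, 16 + gap),
                                       amp_g = 0.02))
  }
  ev_merge <- detect_gestures(two(0.5), all_stationary_labels(two(0.5)))
  expect_equal(nrow(ev_merge), 1)

  ev_split <- detect_gestures(two(1.5), all_stationary_labels(two(1.5)))
  expect_equal(nrow(ev_split), 2)
})

test_that("ambulatory time never produces gesture events", {
  sch <- tibble::tibble(state = "walking", start_s = 0, end_s = 300)
  sim <- simulate_recording(sch, signal_params(), seed = 8)
  labs <- schedule_sample_labels(sim$recording, sch)
  # the walking signal is far above threshold, yet no events are emitted
  expect_gt(mean(moving_sd(accel_magnitude(sim$recording))$sd_g > 0.01), 0.99)
  ev <- detect_gestures(sim$recording, labs)
  expect_equal(nrow(ev), 0)
})

test_that("detected events are confined to stationary time and sorted", {
  sch <- tibble::tibble(state = c("sitting", "walking", "sitting"),
                        start_s = c(0, 600, 1200), end_s = c(600, 1200, 1800))
  sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 30), seed = 5)
  labs <- schedule_sample_labels(sim$recording, sch)
  ev <- detect_gestures(sim$recording, labs)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$end_s <= 600 + 1e-9 | ev$start_s >= 1200))
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$end_s[-nrow(ev)] <= ev$start_s[-1] + 1e-9))
})

test_that("detector output is invariant under rotation of the raw axes", {
  rec <- burst_recording(40, tibble::tibble(start_s = c(5, 20),
                                            end_s = c(8, 24), amp_g = 0.04))
  labs <- all_stationary_labels(rec)
  ev0 <- detect_gestures(rec, labs)
  set.seed(123)
  for (k in 1:3) {
    evr <- detect_gestures(rotate_recording(rec, random_rotation()), labs)
    expect_equal(evr$start_s, ev0$start_s)
    expect_equal(evr$end_s, ev0$end_s)
    expect_equal(evr$power_g2, ev0$power_g2, tolerance = 1e-9)
  }
})

test_that("raising the SD threshold never increases eligible windows", {
  sch <- tibble::tibble(state = "sitting", start_s = 0, end_s = 600)
  sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 30,
                                               idle_noise_sd_g = 0.008),
                            seed = 21)
  sds <- moving_sd(accel_magnitude(sim$recording))
  counts <- vapply(c(0.005, 0.01, 0.02, 0.04), function(thr) {
    sum(sds$sd_g > thr)
  }, 1.0)
  expect_true(all(diff(counts) <= 0))
})

test_that("gesture power matches hand computations and the variance identity", {
  expect_equal(gesture_power(c(1, 1, 1)), 0)
  expect_equal(gesture_power(c(0.9, 1.1)), 0.02)
  expect_error(gesture_power(1.0), "at least 2")
  set.seed(4)
  for (k in 1:20) {
    x <- rlnorm(sample(5:200, 1))
    pop_var <- mean((x - mean(x))^2)
    expect_equal(gesture_power(x), length(x) * pop_var, tolerance = 1e-12)
  }
})

test_that("daily gesture counts assign events by start time and conserve totals", {
  segs <- tibble::tibble(date_index = 0:2, start_s = (0:2) * 86400,
                         end_s = (1:3) * 86400, wear_h = 24, n_samples = 0L)
  none <- tibble::tibble(start_s = numeric())
  expect_equal(daily_gesture_counts(none, segs)$gesture_count, c(0L, 0L, 0L))

  # event starting 1 s before midnight counts in the earlier day
  ev <- tibble::tibble(start_s = c(86399, 86400, 100))
  counts <- daily_gesture_counts(ev, segs)$gesture_count
  expect_equal(counts, c(2L, 1L, 0L))

  set.seed(9)
  ev <- tibble::tibble(start_s = runif(200, 0, 3 * 86400))
  expect_equal(sum(daily_gesture_counts(ev, segs)$gesture_count), 200L)
})

test_that("misaligned labels are rejected", {
  rec <- flat_recording(10)
  labs <- all_stationary_labels(rec)[1:10, ]
  expect_error(detect_gestures(rec, labs), "aligned")
})
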