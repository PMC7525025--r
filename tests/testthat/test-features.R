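test_that("activity-time ratio follows its definition and conserves with stationary", {
  rec <- flat_recording(3600)
  labs <- all_stationary_labels(rec, "walking")
  expect_equal(activity_time_ratio(labs, covered_time_s(rec)), 1.0)

  # 6 h walking in 24 h covered -> 0.25
  labs <- tibble::tibble(
    time_s = 0, binary = rep(c("ambulatory", "stationary"), c(6, 18)))
  expect_equal(activity_time_ratio(labs, 24 / 20, sample_rate_hz = 20), 0.25)

  expect_error(activity_time_ratio(labs, 0), "positive")

  # fully classified recording: ambulatory + stationary ratios sum to 1
  set.seed(1)
  labs <- tibble::tibble(time_s = 0,
                         binary = sample(c("ambulatory", "stationary"), 500,
                                         replace = TRUE))
  mon <- 500 / 20
  amb <- activity_time_ratio(labs, mon)
  stat_labs <- labs
  stat_labs$binary <- ifelse(labs$binary == "ambulatory", "stationary",
                             "ambulatory")
  expect_equal(amb + activity_time_ratio(stat_labs, mon), 1.0)
})

test_that("median daily gesture count applies the even rule and valid-day filter", {
  daily <- tibble::tibble(gesture_count = c(3, 5, 7), wear_h = 20)
  expect_equal(median_daily_gesture_count(daily), 5)
  daily4 <- tibble::tibble(gesture_count = c(3, 5, 7, 9), wear_h = 20)
  expect_equal(median_daily_gesture_count(daily4), 6)

  # a day with 2 h of wear is excluded; no qualifying day -> NA, not zero
  daily <- tibble::tibble(gesture_count = c(100, 4), wear_h = c(2, 20))
  expect_equal(median_daily_gesture_count(daily), 4)
  expect_true(is.na(median_daily_gesture_count(
    tibble::tibble(gesture_count = 5, wear_h = 3))))
})

test_that("gesture-power aggregation is a nested median over qualifying days", {
  segs <- tibble::tibble(date_index = 0:2, wear_h = c(20, 20, 2))
  ev <- tibble::tibble(
    start_s = c(10, 20, 86410, 86420, 86430, 2 * 86400 + 10),
    power_g2 = c(0.02, 0.04, 0.1, 0.3, 0.5, 99))
  # day 0 median 0.03, day 1 median 0.3, day 2 excluded (2 h wear)
  expect_equal(aggregate_gesture_power(ev, segs), median(c(0.03, 0.3)))
  # order of events within a day does not matter
  expect_equal(aggregate_gesture_power(ev[sample(6), ], segs),
               aggregate_gesture_power(ev, segs))
  # single event
  expect_equal(aggregate_gesture_power(
    tibble::tibble(start_s = 5, power_g2 = 0.02), segs), 0.02)
  # no events -> missing marker
  expect_true(is.na(aggregate_gesture_power(
    tibble::tibble(start_s = numeric(), power_g2 = numeric()), segs)))

  # brute-force nested-median oracle on random cohorts
  set.seed(7)
  for (k in 1:20) {
    n <- sample(10:80, 1)
    ev <- tibble::tibble(start_s = runif(n, 0, 3 * 86400),
                         power_g2 = rlnorm(n, log(0.05), 1))
    segs <- tibble::tibble(date_index = 0:2, wear_h = runif(3, 0, 24))
    day <- floor(ev$start_s / 86400)
    qual_days <- segs$date_index[segs$wear_h >= 8]
    dm <- vapply(qual_days, function(d) {
      p <- ev$power_g2[day == d]
      if (length(p) == 0) NA_real_ else median(p)
    }, 1.0)
    dm <- dm[!is.na(dm)]
    oracle <- if (length(dm) == 0) NA_real_ else median(dm)
    expect_equal(aggregate_gesture_power(ev, segs), oracle)
  }
})

test_that("doubling deviations about the mean quadruples gesture power", {
  set.seed(3)
  x <- 1 + rnorm(50, 0, 0.05)
  doubled <- mean(x) + 2 * (x - mean(x))
  expect_equal(gesture_power(doubled), 4 * gesture_power(x), tolerance = 1e-12)
})

test_that("patient_features assembles a deterministic one-row summary", {
  sch <- tibble::tibble(state = c("sitting", "walking", "sitting"),
                        start_s = c(0, 600, 1200), end_s = c(600, 1200, 1800))
  sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 30),
                            seed = 5, patient_id = "px")
  labs <- schedule_sample_labels(sim$recording, sch)
  ev <- detect_gestures(sim$recording, labs)
  f1 <- patient_features(sim$recording, labs, ev, min_wear_h = 0.2,
                         study_hours = 1)
  f2 <- patient_features(sim$recording, labs, ev, min_wear_h = 0.2,
                         study_hours = 1)
  expect_identical(f1, f2)
  expect_equal(f1$patient_id, "px")
  expect_equal(f1$activity_time_ratio, 1 / 3, tolerance = 0.01)
  expect_equal(f1$monitoring_ratio, 0.5)
  expect_gt(f1$median_daily_gesture_count, 0)
})
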