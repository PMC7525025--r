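test_that("schedules conserve time exactly and respect the wear target", {
  sch <- simulate_schedule(1, monitoring_target = 1, seed = 1)
  expect_equal(sum(sch$end_s - sch$start_s), 86400)
  expect_false(any(sch$state == "non_wear"))
  expect_silent(validate_schedule(sch))

  sch3 <- simulate_schedule(3, monitoring_target = 1, seed = 2)
  expect_equal(sum(sch3$end_s - sch3$start_s), 3 * 86400)

  # realized wear over 50 seeds lands within 5% of the 0.74 target
  wear_frac <- vapply(1:50, function(s) {
    sc <- simulate_schedule(1, monitoring_target = 0.74, seed = s)
    sum((sc$end_s - sc$start_s)[sc$state != "non_wear"]) / 86400
  }, 1.0)
  expect_lt(abs(mean(wear_frac) - 0.74), 0.05 * 0.74)
})

test_that("schedules are deterministic given a seed and reject bad input", {
  expect_identical(simulate_schedule(2, seed = 7), simulate_schedule(2, seed = 7))
  expect_error(simulate_schedule(0), "whole number")
  expect_error(simulate_schedule(1, monitoring_target = 0), "monitoring_target")
  bad <- tibble::tibble(state = c("sitting", "sitting"),
                        start_s = c(0, 50), end_s = c(100, 150))
  expect_error(validate_schedule(bad), "contiguous|sorted")
})

test_that("stationary signal stays below the 0.01 g moving-SD threshold and gait far above", {
  lying <- tibble::tibble(state = "lying_down", start_s = 0, end_s = 600)
  sim <- simulate_recording(lying, signal_params(gesture_rate_per_h = 0), seed = 3)
  sds <- moving_sd(accel_magnitude(sim$recording))
  expect_true(all(sds$sd_g < 0.01))

  walking <- tibble::tibble(state = "walking", start_s = 0, end_s = 600)
  simw <- simulate_recording(walking, signal_params(), seed = 3)
  sdw <- moving_sd(accel_magnitude(simw$recording))
  expect_gt(mean(sdw$sd_g > 0.01), 0.99)
  expect_equal(nrow(simw$truth_events), 0)
})

test_that("noise-free stationary signal has constant 1 g magnitude", {
  sch <- tibble::tibble(state = "sitting", start_s = 0, end_s = 60)
  p <- signal_params(idle_noise_sd_g = 0, gesture_rate_per_h = 0)
  sim <- simulate_recording(sch, p, seed = 1)
  expect_lt(max(abs(accel_magnitude(sim$recording)$m_g - 1)), 1e-12)
})

test_that("signal params enforce the detectability premise", {
  expect_error(signal_params(idle_noise_sd_g = 0.02), "0.01")
  expect_error(signal_params(gesture_amp_sd_g = 0.005), "detectable")
  expect_error(signal_params(gesture_dur_s_range = c(5, 1)), "min, max")
})

test_that("planted gesture events lie inside quiet stationary bouts", {
  sch <- simulate_schedule(1, monitoring_target = 0.9, seed = 11)
  sim <- simulate_recording(sch, signal_params(gesture_rate_per_h = 8), seed = 11)
  ev <- sim$truth_events
  expect_gt(nrow(ev), 0)
  quiet <- sch[sch$state %in% c("sitting", "standing", "lying_down"), ]
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    any(quiet$start_s <= ev$start_s[i] & ev$end_s[i] <= quiet$end_s + 1e-6)
  }, TRUE)
  expect_true(all(inside))
  # events are sorted, non-overlapping, with positive power
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$power_g2 >= 0))
})

test_that("planted event counts follow the configured Poisson rate", {
  sch <- tibble::tibble(state = "sitting", start_s = 0, end_s = 1800)
  rate <- 20 # per hour over 0.5 h => Poisson(10)
  counts <- vapply(1:100, function(s) {
    nrow(simulate_recording(sch, signal_params(gesture_rate_per_h = rate),
                            seed = s)$truth_events)
  }, 1.0)
  lambda <- rate * 0.5
  se <- sqrt(lambda / 100)
  # rejected placements (overlap rule) thin the process slightly; 3 SE band
  expect_lt(abs(mean(counts) - lambda), 3 * se + 0.5)
})

test_that("signal synthesis is deterministic given a seed", {
  sch <- tibble::tibble(state = c("sitting", "walking"),
                        start_s = c(0, 300), end_s = c(300, 600))
  s1 <- simulate_recording(sch, signal_params(), seed = 5)
  s2 <- simulate_recording(sch, signal_params(), seed = 5)
  expect_identical(tibble::as_tibble(s1$recording), tibble::as_tibble(s2$recording))
  expect_identical(s1$truth_events, s2$truth_events)
})
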