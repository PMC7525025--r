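#' Simulate a multi-day activity schedule
#'
#' Builds a contiguous, non-overlapping sequence of activity bouts covering
#' `days` x 24 h from the study origin. Each day has a night-time lying bout,
#' minutes-scale daytime bouts alternating among the eight activity states,
#' and (when `monitoring_target < 1`) explicit `non_wear` entries placed
#' during the day so the realized monitoring ratio lands near the target.
#' Durations are rounded to whole seconds, so bout durations sum exactly to
#' `days * 86400` s.
#'
#' @param days Number of 24-h days (>= 1).
#' @param params A [signal_params()] object (used for reproducibility of the
#'   downstream signal; the schedule itself only needs the state vocabulary).
#' @param monitoring_target Fraction of time the device is worn; `non_wear`
#'   gaps are planted to approximate it (default 0.74, the wear level typical
#'   of multi-week wrist actigraphy in outpatients).
#' @param state_probs Named sampling weights over daytime bout states.
#' @param seed Integer seed; identical seeds give identical schedules.
#' @return A tibble with columns `state`, `start_s`, `end_s`, sorted and
#'   contiguous over `[0, days * 86400)`.
#' @examples
#' sch <- simulate_schedule(1, monitoring_target = 1, seed = 1)
#' sum(sch$end_s - sch$start_s) # 86400
#' @export
simulate_schedule <- function(days,
                              params = signal_params(),
                              monitoring_target = 0.74,
                              state_probs = c(sitting = 0.34, standing = 0.13,
                                              hand_work = 0.12, lying_down = 0.05,
                                              walking = 0.17, climbing_stairs = 0.05,
                                              cycling = 0.08, jogging = 0.06),
                              seed = NULL) {
  if (!is.numeric(days) || length(days) != 1 || days < 1 || days != round(days)) {
    abort("`days` must be a positive whole number")
  }
  if (monitoring_target <= 0 || monitoring_target > 1) {
    abort("`monitoring_target` must be in (0, 1]")
  }
  if (!all(names(state_probs) %in% ACTIVITY_STATES)) {
    abort("`state_probs` names must be fine activity states")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  withr::with_seed(seed, {
    day_tbls <- purrr::map(seq_len(days) - 1L, function(d) {
      simulate_one_day(d * SECONDS_PER_DAY, monitoring_target, state_probs)
    })
    dplyr::bind_rows(day_tbls)
  })
}

# bout duration model, seconds; minutes-scale dwell times per state
bout_duration_s <- function(state) {
  rng <- switch(state,
    sitting = c(300, 2400), standing = c(120, 900),
    hand_work = c(300, 1800), lying_down = c(600, 2400),
    walking = c(120, 900), climbing_stairs = c(60, 240),
    cycling = c(300, 1500), jogging = c(300, 1200),
    c(300, 1200))
  round(runif(1, rng[1], rng[2]))
}

simulate_one_day <- function(day_start, monitoring_target, state_probs) {
  day_end <- day_start + SECONDS_PER_DAY
  wake <- day_start + round(runif(1, 6.5, 8) * 3600)
  bed <- day_start + round(runif(1, 22.5, 23.5) * 3600)
  entries <- list(tibble(state = "lying_down", start_s = day_start, end_s = wake))
  t <- wake
  states <- names(state_probs)
  while (t < bed) {
    st <- sample(states, 1, prob = state_probs)
    dur <- min(bout_duration_s(st), bed - t)
    entries[[length(entries) + 1]] <-
      tibble(state = st, start_s = t, end_s = t + dur)
    t <- t + dur
  }
  entries[[length(entries) + 1]] <-
    tibble(state = "lying_down", start_s = bed, end_s = day_end)
  sched <- dplyr::bind_rows(entries)

  if (monitoring_target < 1) {
    gap_total <- round((1 - monitoring_target) * SECONDS_PER_DAY *
                         runif(1, 0.9, 1.1))
    n_gaps <- sample(1:3, 1)
    w <- runif(n_gaps)
    gap_durs <- round(gap_total * w / sum(w))
    placed <- matrix(numeric(0), ncol = 2)
    for (g in gap_durs) {
      if (g < 60) next
      for (try in 1:25) {
        s <- round(runif(1, wake, bed - g))
        e <- s + g
        if (nrow(placed) == 0 ||
            all(e <= placed[, 1] | s >= placed[, 2])) {
          placed <- rbind(placed, c(s, e))
          sched <- overlay_state(sched, s, e, NON_WEAR)
          break
        }
      }
    }
  }
  dplyr::arrange(sched, .data$start_s)
}

# replace [start, end) of a contiguous schedule with `state`, splitting
# overlapped entries
overlay_state <- function(sched, start, end, state) {
  pieces <- purrr::pmap(sched, function(state, start_s, end_s) {
    st <- state
    out <- list()
    if (end_s <= start || start_s >= end) {
      return(list(tibble(state = st, start_s = start_s, end_s = end_s)))
    }
    if (start_s < start) {
      out[[length(out) + 1]] <- tibble(state = st, start_s = start_s, end_s = start)
    }
    if (end_s > end) {
      out[[length(out) + 1]] <- tibble(state = st, start_s = end, end_s = end_s)
    }
    out
  })
  dplyr::bind_rows(
    dplyr::bind_rows(purrr::flatten(pieces)),
    tibble(state = state, start_s = start, end_s = end)
  ) %>%
    dplyr::arrange(.data$start_s)
}

#' Validate schedule invariants
#'
#' Checks entries are sorted, non-overlapping, contiguous, with positive
#' durations and known states.
#'
#' @param schedule A schedule tibble (`state`, `start_s`, `end_s`).
#' @return The schedule, invisibly; aborts on violation.
#' @export
validate_schedule <- function(schedule) {
  req <- c("state", "start_s", "end_s")
  if (!all(req %in% names(schedule))) {
    abort("schedule needs columns state, start_s, end_s")
  }
  if (any(schedule$end_s <= schedule$start_s)) {
    abort("schedule entries must have end_s > start_s")
  }
  if (is.unsorted(schedule$start_s, strictly = TRUE)) {
    abort("schedule entries must be sorted by start_s")
  }
  if (nrow(schedule) > 1 &&
      any(abs(schedule$start_s[-1] - schedule$end_s[-nrow(schedule)]) > 1e-9)) {
    abort("schedule entries must be contiguous (non-wear is an explicit state)")
  }
  unknown <- setdiff(unique(schedule$state), c(ACTIVITY_STATES, NON_WEAR))
  if (length(unknown) > 0) {
    abort(paste0("unknown states: ", paste(unknown, collapse = ", ")))
  }
  invisible(schedule)
}
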