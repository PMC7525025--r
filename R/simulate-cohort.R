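#' Cohort-generator configuration
#'
#' Configures a synthetic outpatient cohort: per-patient behavioural
#' parameters (gesture rate, ambulatory fraction, per-event power scale,
#' wear), clinical scores (BNSS total, apathy index, diminished expression;
#' PANSS NSFS and PSFS) and effort-choice behaviour, coupled through a
#' Gaussian copula so that requested rank correlations between behavioural
#' latents and scores are planted exactly at the latent level.
#'
#' The copula is a two-factor model (a severity factor behind the clinical
#' scores and a motivation factor behind activity and effort choice), which
#' is positive semi-definite by construction; a coupling target that would
#' need a factor loading above 1 in magnitude is rejected as infeasible.
#'
#' @param n_patients Number of patients (>= 3; default 33).
#' @param days_per_patient Monitored days per patient (default 28).
#' @param coupling Named rank-correlation targets, each in `[-1, 1]`:
#'   `gesture_bnss` (gesture-rate latent vs BNSS total, default -0.44),
#'   `power_dimexp` (gesture-power latent vs diminished expression, default
#'   -0.42), `activity_effort` (ambulatory-fraction latent vs high-effort
#'   choice latent, default 0.58), `severity_motivation` (between the two
#'   factors, default -0.2 — weak enough that effort choice and clinical
#'   scores stay essentially uncorrelated, as observed clinically).
#' @param monitoring_target Mean wear fraction (default 0.74).
#' @param score_ranges Named list of `c(lo, hi)` instrument ranges.
#' @param trial_reps Repetitions of the 18-condition effort-choice grid
#'   (3 press counts x 3 reward levels x 2 probabilities; default 2).
#' @param missing Named integer vector `c(choice = , sensor = )`: patients
#'   with the respective assessments missing (default none).
#' @param seed Integer seed.
#' @return List of class `gw_cohort_config`.
#' @export
cohort_config <- function(n_patients = 33, days_per_patient = 28,
                          coupling = c(gesture_bnss = -0.44,
                                       power_dimexp = -0.42,
                                       activity_effort = 0.58,
                                       severity_motivation = -0.2),
                          monitoring_target = 0.74,
                          score_ranges = list(
                            bnss_total = c(13, 78),
                            bnss_apathy = c(0, 42),
                            bnss_diminished_expression = c(0, 36),
                            panss_nsfs = c(7, 49),
                            panss_psfs = c(7, 49)),
                          trial_reps = 2,
                          missing = c(choice = 0, sensor = 0),
                          seed = NULL) {
  if (n_patients < 3) abort("n_patients must be >= 3")
  defaults <- c(gesture_bnss = -0.44, power_dimexp = -0.42,
                activity_effort = 0.58, severity_motivation = -0.2)
  coupling <- modifyList(as.list(defaults), as.list(coupling))
  coupling <- unlist(coupling[names(defaults)])
  if (any(abs(coupling) > 1)) {
    abort("rank-correlation targets must lie in [-1, 1]")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  structure(list(
    n_patients = n_patients, days_per_patient = days_per_patient,
    coupling = coupling, monitoring_target = monitoring_target,
    score_ranges = score_ranges, trial_reps = trial_reps,
    missing = missing, seed = seed
  ), class = "gw_cohort_config")
}

# Spearman -> Pearson correlation of the underlying bivariate normal
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# loadings of the 8 copula observables on the (severity, motivation) factors
copula_loadings <- function(coupling) {
  r_sm <- spearman_to_pearson(coupling[["severity_motivation"]])
  lam_total <- 0.9
  lam_dimexp <- 0.88
  lam_gest <- spearman_to_pearson(coupling[["gesture_bnss"]]) / lam_total
  lam_pow <- spearman_to_pearson(coupling[["power_dimexp"]]) / lam_dimexp
  lam_act <- spearman_to_pearson(coupling[["activity_effort"]]) / 0.85
  L <- rbind(
    gesture_rate = c(lam_gest, 0),
    power_scale  = c(lam_pow, 0),
    activity     = c(0, lam_act),
    effort       = c(0, 0.85),
    bnss_total   = c(lam_total, 0),
    bnss_dimexp  = c(lam_dimexp, 0),
    bnss_apathy  = c(0.75, -0.2),
    nsfs         = c(0.8, 0),
    psfs         = c(0.15, 0)
  )
  R <- matrix(c(1, r_sm, r_sm, 1), 2)
  commonality <- rowSums((L %*% R) * L)
  if (any(abs(L) > 1) || any(commonality > 1)) {
    abort(paste0("infeasible coupling: the implied correlation matrix is not ",
                 "positive semi-definite (a factor loading exceeds 1)"))
  }
  Sigma <- L %*% R %*% t(L) + diag(1 - commonality)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("infeasible coupling: correlation matrix not positive semi-definite")
  }
  list(L = L, R = R, uniq = 1 - commonality)
}

# draw n rows of the copula's uniform marginals
draw_copula <- function(n, coupling) {
  cp <- copula_loadings(coupling)
  f <- matrix(rnorm(n * 2), n) %*% chol(cp$R)
  z <- f %*% t(cp$L) +
    matrix(rnorm(n * nrow(cp$L)), n) %*% diag(sqrt(cp$uniq))
  colnames(z) <- rownames(cp$L)
  list(z = z, u = pnorm(z))
}

qbeta_range <- function(u, range, mean_frac, sd_frac) {
  v <- sd_frac^2
  ab <- mean_frac * (1 - mean_frac) / v - 1
  lo <- range[1]; hi <- range[2]
  lo + (hi - lo) * qbeta(u, ab * mean_frac, ab * (1 - mean_frac))
}

#' Generate a synthetic cohort
#'
#' Draws per-patient latent traits from the configured copula and expands
#' them into (i) a clinical-scores table, (ii) effort-choice trial logs whose
#' high-effort probability is monotone in the motivation latent, and (iii)
#' day-level sensor summaries: per-day wear hours around the monitoring
#' target, ambulatory hours, Poisson gesture counts driven by the patient's
#' gesture rate over stationary time, and lognormal per-event powers. All
#' randomness is governed by the config seed.
#'
#' Day-level resolution is deliberate: the correlation stage consumes
#' per-patient features, and multi-week raw signal adds nothing but runtime
#' there. Use [simulate_recording()] for signal-level recordings.
#'
#' @param config A [cohort_config()].
#' @return List of class `gw_cohort_sim` with tibbles `patients` (latent
#'   traits and behavioural parameters), `scores`, `trials`, `daily`,
#'   `events`, and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "gw_cohort_config")) {
    abort("`config` must come from cohort_config()")
  }
  n <- config$n_patients
  sr <- config$score_ranges
  withr::with_seed(config$seed, {
    cop <- draw_copula(n, config$coupling)
    u <- cop$u; z <- cop$z
    ids <- sprintf("p%03d", seq_len(n))

    patients <- tibble(
      patient_id = ids,
      gesture_rate_per_h = qlnorm(u[, "gesture_rate"], log(6), 0.5),
      power_scale_g2 = qlnorm(u[, "power_scale"], log(0.03), 0.5),
      ambulatory_frac = qbeta_range(u[, "activity"], c(0, 1), 0.12, 0.05),
      p_high_effort = plogis(qlogis(0.55) + 1.3 * z[, "effort"]),
      monitoring_ratio_true = qbeta_range(runif(n), c(0, 1),
                                          config$monitoring_target, 0.08)
    )

    scores <- tibble(
      patient_id = ids,
      bnss_total = round(qbeta_range(u[, "bnss_total"], sr$bnss_total,
                                     0.354, 0.177)),
      bnss_apathy = round(qbeta_range(u[, "bnss_apathy"], sr$bnss_apathy,
                                      0.45, 0.2)),
      bnss_diminished_expression = round(qbeta_range(
        u[, "bnss_dimexp"], sr$bnss_diminished_expression, 0.45, 0.2)),
      panss_nsfs = round(qbeta_range(u[, "nsfs"], sr$panss_nsfs, 0.381, 0.083)),
      panss_psfs = round(qbeta_range(u[, "psfs"], sr$panss_psfs, 0.29, 0.114))
    )
    validate_clinical_scores(scores)

    trials <- simulate_trials(patients, config$trial_reps)
    sensor <- simulate_daily(patients, config$days_per_patient)
  })
  structure(list(patients = patients, scores = scores, trials = trials,
                 daily = sensor$daily, events = sensor$events,
                 config = config),
            class = "gw_cohort_sim")
}

simulate_trials <- function(patients, reps) {
  grid <- tidyr::expand_grid(
    offered_presses = c(100, 120, 150),
    offered_points = c(3, 5, 7),
    reward_probability = c(0.5, 1.0),
    rep = seq_len(reps)
  )
  k <- nrow(grid)
  n <- nrow(patients)
  trials <- dplyr::bind_cols(
    tibble(patient_id = rep(patients$patient_id, each = k),
           trial = rep(seq_len(k), n)),
    grid[rep(seq_len(k), n), c("offered_presses", "offered_points",
                               "reward_probability")]
  )
  p <- pmin(pmax(rep(patients$p_high_effort, each = k), 1e-6), 1 - 1e-6)
  lp <- qlogis(p) + 0.1 * (trials$offered_points - 5) -
    0.8 * (trials$reward_probability == 0.5)
  hard <- rbinom(nrow(trials), 1, plogis(lp)) == 1
  dplyr::mutate(trials,
                choice = if_else(hard, "hard", "easy"),
                effort_presses = if_else(hard, .data$offered_presses, 20),
                reward_points = if_else(hard, .data$offered_points, 1))
}

simulate_daily <- function(patients, days) {
  n <- nrow(patients)
  daily <- tibble(
    patient_id = rep(patients$patient_id, each = days),
    date_index = rep(seq_len(days) - 1L, n)
  )
  mr <- rep(patients$monitoring_ratio_true, each = days)
  af <- rep(patients$ambulatory_frac, each = days)
  rate <- rep(patients$gesture_rate_per_h, each = days)
  daily$wear_h <- pmin(24, pmax(0, 24 * mr * runif(n * days, 0.85, 1.15)))
  daily$ambulatory_h <- daily$wear_h * pmin(1, af * runif(n * days, 0.8, 1.2))
  daily$stationary_h <- daily$wear_h - daily$ambulatory_h
  daily$gesture_count <- rpois(n * days, rate * daily$stationary_h)

  tot <- sum(daily$gesture_count)
  events <- if (tot > 0) {
    row_of_event <- rep(seq_len(nrow(daily)), daily$gesture_count)
    scale <- rep(patients$power_scale_g2, each = days)[row_of_event]
    tibble(
      patient_id = daily$patient_id[row_of_event],
      start_s = daily$date_index[row_of_event] * SECONDS_PER_DAY +
        runif(tot, 0, SECONDS_PER_DAY),
      power_g2 = stats::rlnorm(tot, log(scale), 0.6)
    ) %>%
      dplyr::arrange(.data$patient_id, .data$start_s)
  } else {
    tibble(patient_id = character(), start_s = numeric(), power_g2 = numeric())
  }
  list(daily = daily, events = events)
}

#' Assemble the per-patient cohort table
#'
#' Reduces a simulated cohort to one row per patient: the effort-choice
#' score, the four sensor features (computed with the same feature rules the
#' signal pipeline uses: qualifying days need `min_wear_h` hours of wear,
#' medians of daily values), and the clinical scores. Optional missingness
#' (config `missing`) blanks the choice task or all sensor features for
#' randomly chosen patients.
#'
#' @param sim A `gw_cohort_sim` from [simulate_cohort()].
#' @param min_wear_h Valid-day rule (default 8).
#' @return Tibble with one row per patient: features plus scores.
#' @export
assemble_cohort <- function(sim, min_wear_h = 8) {
  if (!inherits(sim, "gw_cohort_sim")) abort("`sim` must be a gw_cohort_sim")
  feats <- sim$daily %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(
      activity_time_ratio = sum(.data$ambulatory_h) / sum(.data$wear_h),
      median_daily_gesture_count = median_daily_gesture_count(
        dplyr::pick("gesture_count", "wear_h"), min_wear_h),
      monitoring_ratio = sum(.data$wear_h) /
        (24 * sim$config$days_per_patient),
      n_days_used = sum(.data$wear_h >= min_wear_h),
      .groups = "drop")
  # vectorized median-of-daily-medians; same rule as aggregate_gesture_power()
  powers <- sim$events %>%
    dplyr::mutate(date_index = floor(.data$start_s / SECONDS_PER_DAY)) %>%
    dplyr::inner_join(sim$daily[c("patient_id", "date_index", "wear_h")],
                      by = c("patient_id", "date_index")) %>%
    dplyr::filter(.data$wear_h >= min_wear_h) %>%
    dplyr::group_by(.data$patient_id, .data$date_index) %>%
    dplyr::summarise(p = median(.data$power_g2), .groups = "drop_last") %>%
    dplyr::summarise(gesture_power_agg = median(.data$p), .groups = "drop")
  choice <- sim$trials %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(high_effort_choice = score_effort_choice(dplyr::pick(
      "choice", "offered_points", "reward_probability")), .groups = "drop")
  cohort <- feats %>%
    dplyr::left_join(powers, by = "patient_id") %>%
    dplyr::left_join(choice, by = "patient_id") %>%
    dplyr::left_join(sim$scores, by = "patient_id")

  miss <- sim$config$missing
  if (any(miss > 0)) {
    cohort <- withr::with_seed(sim$config$seed + 1L, {
      if (miss[["choice"]] > 0) {
        idx <- sample(nrow(cohort), miss[["choice"]])
        cohort$high_effort_choice[idx] <- NA_real_
      }
      if (miss[["sensor"]] > 0) {
        idx <- sample(nrow(cohort), miss[["sensor"]])
        sensor_cols <- c("activity_time_ratio", "median_daily_gesture_count",
                         "gesture_power_agg", "monitoring_ratio")
        cohort[idx, sensor_cols] <- NA_real_
      }
      cohort
    })
  }
  cohort
}
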