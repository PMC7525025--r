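#' Score the effort-choice task
#'
#' In each trial the participant chooses an easy option (press a balloon 20
#' times for 1 point) or a hard option (100, 120 or 150 presses for 3, 5 or
#' 7 points), knowing the reward probability (50% or 100%). The motivated-
#' behaviour score is the percentage of high-effort choices among *qualifying*
#' trials: those offering 5 or 7 points at 100% reward probability, across
#' all effort levels. Non-qualifying trials never enter the denominator.
#'
#' @param trials Tibble with one row per trial: `choice` (`"easy"`/`"hard"`),
#'   `offered_points` (3, 5 or 7 — the hard option's reward on offer),
#'   `reward_probability` (0.5 or 1.0).
#' @return Percent of high-effort choices in `[0, 100]`, or `NA` when no
#'   trial qualifies.
#' @examples
#' trials <- tibble::tibble(
#'   choice = c("hard", "easy", "hard", "hard"),
#'   offered_points = c(5, 7, 3, 7),
#'   reward_probability = c(1, 1, 1, 0.5)
#' )
#' score_effort_choice(trials) # 50: two qualifying trials, one chosen hard
#' @export
score_effort_choice <- function(trials) {
  req <- c("choice", "offered_points", "reward_probability")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trials are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(trials$choice), c("easy", "hard"))
  if (length(bad) > 0) {
    abort(paste0("unknown choice values: ", paste(bad, collapse = ", ")))
  }
  qual <- trials$offered_points %in% c(5, 7) & trials$reward_probability == 1
  if (!any(qual)) return(NA_real_)
  100 * mean(trials$choice[qual] == "hard")
}

#' Dollar bonus from cumulated task points
#'
#' Each completed set of 20 cumulated points converts to a $1 bonus; partial
#' sets earn nothing.
#'
#' @param points_total Non-negative total points.
#' @return Whole dollars.
#' @examples
#' effort_bonus(47) # 2
#' @export
effort_bonus <- function(points_total) {
  if (any(points_total < 0)) abort("points must be non-negative")
  floor(points_total / 20)
}

#' Validate a clinical-scores table
#'
#' Checks instrument ranges: BNSS total within 13-78, PANSS factor scores
#' positive.
#'
#' @param scores Tibble with columns `bnss_total`, `bnss_apathy`,
#'   `bnss_diminished_expression`, `panss_nsfs`, `panss_psfs` (and any id
#'   columns).
#' @return `scores`, invisibly; aborts on violation.
#' @export
validate_clinical_scores <- function(scores) {
  req <- c("bnss_total", "bnss_apathy", "bnss_diminished_expression",
           "panss_nsfs", "panss_psfs")
  missing_cols <- setdiff(req, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("scores are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  in_range <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  if (!in_range(scores$bnss_total, 13, 78)) {
    abort("bnss_total outside the instrument range 13-78")
  }
  if (!in_range(scores$panss_nsfs, 0, Inf) || !in_range(scores$panss_psfs, 0, Inf)) {
    abort("PANSS factor scores must be positive")
  }
  invisible(scores)
}
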