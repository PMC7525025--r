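#' Spearman rank correlation with a two-sided p-value
#'
#' Ranks use average ranks for ties. For n <= 7 complete pairs the p-value is
#' exact: the proportion of all n! permutations of one variable whose
#' absolute rank correlation is at least the observed one. For larger n a
#' two-sided t approximation with n - 2 degrees of freedom is used.
#' Incomplete pairs are dropped listwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_n_max Largest n for which the exact permutation p-value is
#'   computed (default 7).
#' @return List of class `gw_spearman`: `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_test <- function(x, y, exact_n_max = 7) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) {
    abort(sprintf("need at least 4 complete pairs, got %d", n))
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("a variable with all-tied values has no rank correlation")
  }
  rho <- cor(rx, ry)
  if (n <= exact_n_max) {
    rho_all <- perm_rank_cors(rx, ry)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "gw_spearman")
}

# rank correlations of rx against every permutation of ry
perm_rank_cors <- function(rx, ry) {
  n <- length(rx)
  P <- all_permutations(n)              # n! x n index matrix
  ry_perm <- matrix(ry[P], nrow = nrow(P))
  rxc <- rx - mean(rx)
  num <- ry_perm %*% rxc
  den <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
  as.numeric(num) / den
}

# all permutations of 1..n as a matrix, built by inserting n into every
# position of every permutation of 1..(n-1)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  P <- all_permutations(n - 1)
  pieces <- lapply(seq_len(n), function(pos) {
    left <- P[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) P[, pos:(n - 1), drop = FALSE] else
      P[, 0, drop = FALSE]
    cbind(left, n, right)
  })
  do.call(rbind, pieces)
}

#' @export
print.gw_spearman <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

#' @rdname spearman_test
#' @param ... Unused.
#' @method tidy gw_spearman
#' @export
tidy.gw_spearman <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}

#' Correlation table between sensor features and clinical scores
#'
#' Computes Spearman correlations of every digital feature (high-effort
#' choice, activity ratio, gesture power, gesture count) against every
#' clinical score (BNSS apathy index, BNSS diminished expression, BNSS total,
#' PANSS NSFS, PANSS PSFS), with listwise deletion per pair and a per-cell
#' p < 0.05 significance flag (no multiple-testing correction by default,
#' matching the per-cell starring convention of exploratory digital-biomarker
#' tables; Benjamini-Hochberg adjustment is available).
#'
#' @param cohort Tibble with one row per patient containing the feature and
#'   score columns.
#' @param features Named character vector: display name -> column.
#' @param scores Named character vector: display name -> column.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Tibble of class `gw_cor_tbl`: `score`, `feature`, `n`, `rho`,
#'   `p_value`, `significant`.
#' @export
correlation_table <- function(cohort,
                              features = c("High-effort choice" = "high_effort_choice",
                                           "Activity ratio" = "activity_time_ratio",
                                           "Gesture power" = "gesture_power_agg",
                                           "Gesture count" = "median_daily_gesture_count"),
                              scores = c("BNSS Apathy Index" = "bnss_apathy",
                                         "BNSS Diminished Expression" = "bnss_diminished_expression",
                                         "BNSS Total Score" = "bnss_total",
                                         "PANSS NSFS" = "panss_nsfs",
                                         "PANSS PSFS" = "panss_psfs"),
                              p_adjust = c("none", "BH"), alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(cohort) == 0) abort("cohort is empty")
  missing_cols <- setdiff(c(features, scores), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(score = names(scores), feature = names(features))
  res <- purrr::pmap_dfr(grid, function(score, feature) {
    st <- spearman_test(cohort[[features[[feature]]]],
                        cohort[[scores[[score]]]])
    tibble(score = score, feature = feature, n = st$n, rho = st$rho,
           p_value = st$p_value)
  })
  if (p_adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
  }
  res$significant <- res$p_value < alpha
  class(res) <- c("gw_cor_tbl", class(res))
  res
}

#' Pivot a correlation table to the wide scores-by-features layout
#'
#' @param cor_tbl A `gw_cor_tbl`.
#' @param stars Append `*` to significant cells and format to 3 decimals
#'   (returns character columns).
#' @return Wide tibble, one row per clinical score.
#' @export
pivot_correlation <- function(cor_tbl, stars = TRUE) {
  df <- as_tibble(cor_tbl)
  if (stars) {
    df$cell <- sprintf("%.3f%s", df$rho, ifelse(df$significant, "*", ""))
  } else {
    df$cell <- df$rho
  }
  tidyr::pivot_wider(df[c("score", "feature", "cell")],
                     names_from = "feature", values_from = "cell")
}

#' Heatmap of a feature-score correlation table
#'
#' @param object A `gw_cor_tbl`.
#' @param ... Unused.
#' @return A ggplot object: tiles coloured by rho, starred when p < 0.05.
#' @method autoplot gw_cor_tbl
#' @export
autoplot.gw_cor_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- sprintf("%.2f%s", df$rho, ifelse(df$significant, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$score,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
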