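# Table-1-style descriptive machinery: obesity classification, weighted
# prevalence with a Kish effective-sample-size interval, and the two
# comparison tests used for categorical and time variables.

#' Classify obesity from body mass index
#'
#' Applies the WHO criterion: obesity is BMI of 30 kg/m2 or more (boundary
#' inclusive).
#'
#' @param bmi body mass index values (kg/m2), finite and positive.
#' @return Integer 0/1 flags.
#' @export
classify_obesity <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    .stopf("domain error: BMI must be finite and positive")
  as.integer(bmi >= 30)
}

#' Survey-weighted prevalence with a logit-scale Wald interval
#'
#' Estimates `sum(w*y)/sum(w)` and builds a 95\% interval on the logit scale
#' using the Kish effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param flags binary 0/1 outcomes.
#' @param weights positive expansion factors, same length as `flags`.
#' @param level confidence level.
#' @return List with `estimate`, `ci_low`, `ci_high`, `n`, `n_eff`.
#' @export
weighted_prevalence <- function(flags, weights = rep(1, length(flags)), level = 0.95) {
  if (length(flags) == 0L) .stopf("domain error: empty input")
  if (length(flags) != length(weights)) .stopf("flags and weights must have equal length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    .stopf("domain error: weights must be positive")
  if (!all(flags %in% c(0, 1))) .stopf("flags must be binary 0/1")
  p <- sum(weights * flags) / sum(weights)
  n_eff <- sum(weights)^2 / sum(weights^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (p <= 0 || p >= 1) {
    ci <- c(p, p)
  } else {
    se_logit <- sqrt(1 / (n_eff * p * (1 - p)))
    ci <- stats::plogis(stats::qlogis(p) + c(-1, 1) * z * se_logit)
  }
  structure(list(estimate = p, ci_low = ci[1], ci_high = ci[2],
                 n = length(flags), n_eff = n_eff),
            class = "gsem_prevalence")
}

#' @export
print.gsem_prevalence <- function(x, ...) {
  cat(sprintf("Weighted prevalence: %.3f (95%%CI %.3f; %.3f), n = %d, effective n = %.1f\n",
              x$estimate, x$ci_low, x$ci_high, x$n, x$n_eff))
  invisible(x)
}

.test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method),
            class = "gsem_test")
}

#' @export
print.gsem_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g\n", x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df), x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson test without continuity correction, as used for the
#' categorical rows of a stratified descriptive table.
#'
#' @param table matrix of nonnegative counts, at least 2 x 2.
#' @return A test result with `statistic`, `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    .stopf("domain error: contingency table needs at least 2 rows and 2 columns")
  if (any(table < 0) || any(!is.finite(table)))
    .stopf("domain error: counts must be nonnegative and finite")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("domain error: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .test_result(ct$statistic, unname(ct$parameter), ct$p.value, "Pearson chi-square")
}

#' Mann-Whitney U test (normal approximation)
#'
#' Two-sided rank-sum comparison with tie and continuity corrections. The
#' statistic is the U of the first sample.
#'
#' @param x,y numeric samples, both nonempty.
#' @return A test result; `df` is `NA` for this rank test.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) .stopf("domain error: empty sample")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  .test_result(wt$statistic, NA_integer_, wt$p.value, "Mann-Whitney U")
}

#' Stratified descriptive table
#'
#' Builds a Table-1-style summary stratified by a binary outcome: column
#' percentages (unweighted and weighted) with chi-square p-values for
#' categorical covariates, and medians with Mann-Whitney p-values for
#' time variables. Because survey reports differ on whether such tables are
#' weighted, both versions are returned side by side.
#'
#' @param data person-level data frame.
#' @param outcome name of the binary stratifying column.
#' @param cat_vars categorical covariate names.
#' @param time_vars continuous (minutes/week) variable names.
#' @param weights optional name of the expansion-factor column.
#' @return Data frame with one row per category or time variable.
#' @export
describe_table <- function(data, outcome = "obesity",
                           cat_vars = c("sex", "ethnicity", "schooling", "wealth_quartile"),
                           time_vars = c("computer_smartphone", "tv", "video_games",
                                         "motor_vehicle", "cycling", "walking",
                                         "leisure_pa"),
                           weights = NULL) {
  y <- data[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1))) .stopf("outcome column must be binary 0/1")
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  rows <- list()
  for (v in intersect(cat_vars, names(data))) {
    f <- factor(data[[v]])
    tab <- table(f, factor(y, levels = c(1, 0)))
    p <- tryCatch(chi_square_test(tab)$p_value, error = function(e) NA_real_)
    for (lev in levels(f)) {
      sel <- f == lev
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, type = "categorical",
        pct_obese = 100 * sum(sel & y == 1) / max(sum(y == 1), 1),
        pct_non = 100 * sum(sel & y == 0) / max(sum(y == 0), 1),
        pct_total = 100 * mean(sel),
        wpct_obese = 100 * sum(w * (sel & y == 1)) / max(sum(w * (y == 1)), 1e-12),
        wpct_non = 100 * sum(w * (sel & y == 0)) / max(sum(w * (y == 0)), 1e-12),
        wpct_total = 100 * sum(w * sel) / sum(w),
        median_obese = NA_real_, median_non = NA_real_,
        p_value = if (lev == levels(f)[1]) p else NA_real_)
    }
  }
  for (v in intersect(time_vars, names(data))) {
    x1 <- data[[v]][y == 1]; x0 <- data[[v]][y == 0]
    p <- if (length(x1) && length(x0)) mann_whitney_u(x1, x0)$p_value else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "min/week", type = "time",
      pct_obese = NA_real_, pct_non = NA_real_, pct_total = NA_real_,
      wpct_obese = NA_real_, wpct_non = NA_real_, wpct_total = NA_real_,
      median_obese = stats::median(x1), median_non = stats::median(x0),
      p_value = p)
  }
  do.call(rbind, rows)
}
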