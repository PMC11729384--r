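# Department-level aggregation for prevalence/adherence mapping: join-ready
# attribute tables, not rendered maps.

#' Quartile bins of a numeric vector
#'
#' Bins values at their empirical quartiles (type-7 quantiles, left-closed
#' intervals: a value equal to a cut point takes the upper bin). A degenerate
#' input (all values equal) yields all bin 1 with a warning.
#'
#' @param values numeric vector, length at least 4.
#' @return Integer bins 1-4.
#' @export
quartile_bins <- function(values) {
  if (length(values) < 4L) .stopf("domain error: need at least 4 values")
  if (any(!is.finite(values))) .stopf("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (q[1] == q[3]) {
    .warnf("degenerate distribution: quartile cut points coincide")
    if (all(values == values[1])) return(rep(1L, length(values)))
  }
  bins <- 1L + (values >= q[1]) + (values >= q[2]) + (values >= q[3])
  as.integer(bins)
}

#' Department-level prevalence and adherence summary
#'
#' Aggregates person-level records into one row per department: weighted
#' obesity prevalence (in percent, with its interval and effective n),
#' unweighted median adherence score per latent, quartile bins of both, and
#' a flag for departments above the national (weight-combined) average.
#' Departments with zero records are omitted with a warning. The output is a
#' join-ready attribute table keyed by department code; choropleth rendering
#' is left to GIS tools.
#'
#' @param records data frame with `department` and a binary outcome column.
#' @param scores optional data frame from [eb_scores()] aligned row-by-row
#'   with `records`.
#' @param weights optional name of the expansion-factor column in `records`.
#' @param outcome name of the binary outcome column.
#' @return Data frame, one row per nonempty department, with attribute
#'   `national_prevalence` (percent).
#' @export
department_summary <- function(records, scores = NULL, weights = NULL,
                               outcome = "obesity") {
  if (!"department" %in% names(records)) .stopf("records must carry a 'department' column")
  y <- records[[outcome]]
  if (is.null(y) || !all(y %in% c(0, 1))) .stopf("outcome column must be binary 0/1")
  w <- if (is.null(weights)) rep(1, nrow(records)) else records[[weights]]
  dep <- records$department
  if (!is.factor(dep)) dep <- factor(dep)
  empty <- setdiff(levels(dep), unique(as.character(dep)))
  if (length(empty))
    .warnf("omitting departments with zero records: %s", paste(empty, collapse = ", "))
  codes <- sort(intersect(levels(dep), unique(as.character(dep))))
  score_cols <- if (!is.null(scores)) grep("_mean$", names(scores), value = TRUE) else character(0)
  rows <- lapply(codes, function(cd) {
    sel <- dep == cd
    wp <- weighted_prevalence(y[sel], w[sel])
    row <- data.frame(department = cd, n = sum(sel), n_eff = wp$n_eff,
                      prevalence = 100 * wp$estimate,
                      prev_ci_low = 100 * wp$ci_low, prev_ci_high = 100 * wp$ci_high)
    for (scn in score_cols) {
      lat <- sub("_mean$", "", scn)
      row[[paste0("median_", lat)]] <- stats::median(scores[[scn]][sel])
    }
    row
  })
  out <- do.call(rbind, rows)
  national <- 100 * weighted_prevalence(y, w)$estimate
  out$above_national <- out$prevalence > national
  if (nrow(out) >= 4L) {
    out$prev_quartile <- quartile_bins(out$prevalence)
    for (scn in score_cols) {
      lat <- sub("_mean$", "", scn)
      out[[paste0(lat, "_quartile")]] <- quartile_bins(out[[paste0("median_", lat)]])
    }
  }
  attr(out, "national_prevalence") <- national
  rownames(out) <- NULL
  out
}
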