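# Empirical-Bayes prediction of per-person latent scores ("adherence") and
# tertile categorization.

#' Empirical-Bayes latent scores
#'
#' Posterior means and SDs of each latent dimension given a person's
#' indicators, covariates and (by default) outcome, under the fitted model,
#' computed with the same adaptive Gauss-Hermite quadrature as the
#' likelihood. The posterior mean is the person's "adherence" to the
#' dimension; tertiles of each score distribution define low / moderate /
#' high adherence categories.
#'
#' @param fitted a converged [fit_gsem()] object with at least one latent.
#' @param newdata optional data frame to score (default: the fitting data).
#'   Records must be complete; with `condition = "full"` the outcome column
#'   is required too.
#' @param condition `"full"` conditions on indicators, covariates and the
#'   outcome (the software-standard empirical-Bayes prediction);
#'   `"indicators"` conditions on the measurement part only.
#' @param quad quadrature nodes per dimension (default: as fitted).
#' @return Data frame with, per latent `<name>`, columns `<name>_mean`,
#'   `<name>_sd` and `<name>_tertile`.
#' @export
eb_scores <- function(fitted, newdata = NULL,
                      condition = c("full", "indicators"), quad = NULL) {
  if (!inherits(fitted, "gsem_fit")) .stopf("'fitted' must be a gsem_fit")
  if (!isTRUE(fitted$converged))
    .stopf("precondition error: empirical-Bayes scores require a converged fit")
  condition <- match.arg(condition)
  if (is.null(quad)) quad <- fitted$quad
  if (fitted$internal$D == 0L) .stopf("spec has no latent dimensions")
  if (is.null(newdata)) {
    model <- fitted$internal
  } else if (condition == "indicators") {
    sub <- gsem_spec(latents = fitted$spec$latents,
                     structural = fitted$spec$structural,
                     reference = fitted$spec$reference,
                     weights = NULL)
    model <- .prepare_model(sub, newdata)
    # map the reduced parameter vector: measurement + structural + psi only
    full <- fitted$internal
    th <- numeric(model$P)
    for (d in seq_len(model$D)) {
      th[model$map$kappa[[d]]] <- fitted$coefficients[full$map$kappa[[d]]]
      th[model$map$lambda[[d]]] <- fitted$coefficients[full$map$lambda[[d]]]
      th[model$map$logshape[[d]]] <- fitted$coefficients[full$map$logshape[[d]]]
    }
    if (!is.null(model$map$gamma)) th[model$map$gamma] <- fitted$coefficients[full$map$gamma]
    th[model$map$psi] <- fitted$coefficients[full$map$psi]
    ev <- .gsem_eval(th, model, quad = quad, eb = TRUE)
    return(.scores_frame(ev$eb, model$lat_names))
  } else {
    model <- .prepare_model(fitted$spec, newdata)
  }
  ev <- .gsem_eval(fitted$coefficients, model, quad = quad, eb = TRUE,
                   use_disease = condition == "full")
  .scores_frame(ev$eb, model$lat_names)
}

.scores_frame <- function(eb, lat_names) {
  out <- data.frame(row.names = seq_len(nrow(eb$mean)))
  for (d in seq_along(lat_names)) {
    nm <- lat_names[d]
    out[[paste0(nm, "_mean")]] <- eb$mean[, d]
    out[[paste0(nm, "_sd")]] <- eb$sd[, d]
    out[[paste0(nm, "_tertile")]] <- adherence_tertiles(eb$mean[, d])
  }
  out
}

#' Adherence tertiles of a score distribution
#'
#' Cuts scores at the empirical 1/3 and 2/3 quantiles
#' (linear-interpolation, type-7 convention) into `low`, `moderate`, `high`
#' categories. Intervals are left-closed, so a score equal to a cut point
#' takes the upper category. A degenerate distribution (all scores equal)
#' yields all-`low` with a warning.
#'
#' @param scores numeric vector, length at least 3.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
adherence_tertiles <- function(scores) {
  if (length(scores) < 3L) .stopf("domain error: need at least 3 scores")
  if (any(!is.finite(scores))) .stopf("scores must be finite")
  q <- stats::quantile(scores, c(1, 2) / 3, type = 7, names = FALSE)
  lv <- c("low", "moderate", "high")
  if (q[1] == q[2]) {
    .warnf("degenerate score distribution: tertile cut points coincide")
    if (all(scores == scores[1])) return(factor(rep("low", length(scores)), levels = lv))
    return(factor(ifelse(scores < q[1], "low", ifelse(scores > q[2], "high", "moderate")),
                  levels = lv))
  }
  cut(scores, breaks = c(-Inf, q, Inf), labels = lv, right = FALSE)
}
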