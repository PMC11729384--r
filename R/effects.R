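# Direct prevalence ratios and product-of-paths indirect effects from a
# fitted model: the Table-2-style output of the analysis.

#' Prevalence ratios of the disease model
#'
#' Exponentiates each disease-model coefficient (covariates and latent
#' dimensions) into a prevalence ratio with a Wald 95\% interval and
#' two-sided p-value on the chosen covariance.
#'
#' @param fitted a converged [fit_gsem()] with a disease model.
#' @param vcov_choice `"robust"` (sandwich, the modified-Poisson default) or
#'   `"model"`.
#' @param level confidence level.
#' @return Data frame with columns `term`, `coef`, `se`, `PR`, `ci_low`,
#'   `ci_high`, `p_value`, `effect` (all `"direct"`).
#' @export
prevalence_ratio_table <- function(fitted, vcov_choice = c("robust", "model"),
                                   level = 0.95) {
  vcov_choice <- match.arg(vcov_choice)
  if (!inherits(fitted, "gsem_fit")) .stopf("'fitted' must be a gsem_fit")
  if (!isTRUE(fitted$converged)) .stopf("precondition error: fit did not converge")
  model <- fitted$internal
  if (!length(model$map$beta_x)) .stopf("spec has no disease model")
  V <- vcov(fitted, type = vcov_choice)
  idx <- c(model$map$beta_x, model$map$beta_L)
  terms <- c(model$x_names,
             if (length(model$map$beta_L)) paste0("L.", model$lat_names))
  b <- fitted$coefficients[idx]
  se <- sqrt(pmax(diag(V)[idx], 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = terms, coef = unname(b), se = unname(se),
             PR = exp(unname(b)),
             ci_low = exp(unname(b - z * se)), ci_high = exp(unname(b + z * se)),
             p_value = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
             effect = "direct")
}

#' Indirect effects through the latent dimensions
#'
#' For each structural covariate and latent dimension, the product of the
#' path into the latent and the latent's disease coefficient,
#' \eqn{\gamma_d \beta_d}, reported on the coefficient (log) scale — not
#' exponentiated, since a product of log-scale coefficients is not itself a
#' log prevalence ratio. Standard errors are first-order delta method:
#' \eqn{se^2 = \beta^2 se(\gamma)^2 + \gamma^2 se(\beta)^2 +
#' 2\gamma\beta\,cov(\gamma,\beta)}.
#'
#' @inheritParams prevalence_ratio_table
#' @return Data frame rows (`effect = "indirect"`); the `PR` column carries
#'   the raw product to mirror the usual table layout.
#' @export
indirect_effects <- function(fitted, vcov_choice = c("robust", "model"),
                             level = 0.95) {
  vcov_choice <- match.arg(vcov_choice)
  if (!inherits(fitted, "gsem_fit")) .stopf("'fitted' must be a gsem_fit")
  if (!isTRUE(fitted$converged)) .stopf("precondition error: fit did not converge")
  model <- fitted$internal
  if (is.null(model$map$gamma) || !length(model$map$beta_L))
    .stopf("indirect effects need structural paths and latent disease coefficients")
  V <- vcov(fitted, type = vcov_choice)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (d in seq_len(model$D)) {
    bi <- model$map$beta_L[d]
    beta <- fitted$coefficients[bi]
    for (sx in seq_along(model$s_names)) {
      gi <- model$map$gamma[d, sx]
      gam <- fitted$coefficients[gi]
      est <- unname(gam * beta)
      v <- beta^2 * V[gi, gi] + gam^2 * V[bi, bi] + 2 * gam * beta * V[gi, bi]
      se <- sqrt(max(unname(v), 0))
      rows[[length(rows) + 1L]] <- data.frame(
        term = sprintf("%s -> %s", model$s_names[sx], model$lat_names[d]),
        coef = est, se = se, PR = est,
        ci_low = est - z * se, ci_high = est + z * se,
        p_value = if (se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_,
        effect = "indirect")
    }
  }
  do.call(rbind, rows)
}

#' Combined direct and indirect effect table
#'
#' Stacks [prevalence_ratio_table()] and (when the model has structural
#' paths) [indirect_effects()] into one Table-2-style data frame. Direct
#' rows are prevalence ratios; indirect rows are log-scale coefficient
#' products with delta-method intervals.
#'
#' @inheritParams prevalence_ratio_table
#' @return Data frame of effects.
#' @export
effect_table <- function(fitted, vcov_choice = c("robust", "model"), level = 0.95) {
  vcov_choice <- match.arg(vcov_choice)
  out <- prevalence_ratio_table(fitted, vcov_choice, level)
  model <- fitted$internal
  if (!is.null(model$map$gamma) && length(model$map$beta_L))
    out <- rbind(out, indirect_effects(fitted, vcov_choice, level))
  rownames(out) <- NULL
  out
}
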