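# Pre-modelling measurement diagnostics: candidate-distribution goodness of
# fit for the weekly-time indicators, Kaiser-Meyer-Olkin sampling adequacy,
# Bartlett's sphericity test, and exploratory principal-axis loadings.

#' Correlation matrix of log-transformed indicator times
#'
#' Pairwise correlations of `log(time + offset)`, the scale on which the
#' multiplicative Weibull measurement model is linear in the latent variable.
#'
#' @param data person-level data frame.
#' @param indicators indicator column names.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param offset added before the log (indicator times are strictly positive
#'   in synthetic data; real data may carry zeros).
#' @return Correlation matrix with attribute `n` (rows used).
#' @export
indicator_correlations <- function(data,
                                   indicators = c("computer_smartphone", "tv", "video_games",
                                                  "motor_vehicle", "cycling", "walking"),
                                   method = c("pearson", "spearman"),
                                   offset = 1) {
  method <- match.arg(method)
  miss <- setdiff(indicators, names(data))
  if (length(miss)) .stopf("missing indicator columns: %s", paste(miss, collapse = ", "))
  M <- log(as.matrix(data[indicators]) + offset)
  R <- stats::cor(M, method = method)
  attr(R, "n") <- nrow(M)
  R
}

#' Rank candidate distributions for a positive variable
#'
#' Fits each candidate family by maximum likelihood and ranks the fits by
#' AIC; the Kolmogorov-Smirnov statistic against each fitted CDF is reported
#' as an absolute-fit measure. Weekly activity times are strongly
#' right-skewed, and this ranking is how the Weibull family is selected for
#' the measurement models.
#'
#' @param x strictly positive observations, at least 10.
#' @param families subset of `c("weibull", "gamma", "lognormal", "exponential")`.
#' @return Data frame (one row per family, ranked by AIC) with columns
#'   `family`, `aic`, `ks`, `rank` and the fitted parameters in `pars`
#'   (list column). The underlying `fitdistrplus` fits are attached as the
#'   `fits` attribute.
#' @export
distribution_gof <- function(x, families = c("weibull", "gamma", "lognormal", "exponential")) {
  if (any(!is.finite(x)) || any(x <= 0))
    .stopf("domain error: observations must be finite and strictly positive (pre-shift zeros)")
  if (length(x) < 10L) .stopf("domain error: need at least 10 observations")
  families <- match.arg(families, several.ok = TRUE)
  distr <- c(weibull = "weibull", gamma = "gamma", lognormal = "lnorm", exponential = "exp")
  fits <- list()
  rows <- list()
  xs <- sort(x)
  n <- length(xs)
  mx <- mean(x); vx <- stats::var(x)
  for (fam in families) {
    # moment-based starting values stabilise the gamma fit on the extremely
    # skewed times this data produces; other families have safe defaults
    args <- list(data = x, distr = distr[[fam]], method = "mle")
    if (fam == "gamma") {
      args$start <- list(shape = max(mx^2 / vx, 1e-3), rate = max(mx / vx, 1e-10))
      args$optim.method <- "L-BFGS-B"
      args$lower <- c(1e-6, 1e-12)
      args$control <- list(parscale = unlist(args$start))
    }
    if (fam == "exponential") {
      args$start <- list(rate = 1 / mx)
      args$control <- list(parscale = 1 / mx)
    }
    ft <- tryCatch({
      res <- NULL
      utils::capture.output(res <- do.call(fitdistrplus::fitdist, args))
      res
    }, error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$aic)) {
      .warnf("maximum-likelihood fit failed for family '%s'; family skipped", fam)
      next
    }
    cdf <- do.call(match.fun(paste0("p", distr[[fam]])), c(list(xs), as.list(ft$estimate)))
    ks <- max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
    fits[[fam]] <- ft
    rows[[fam]] <- data.frame(family = fam, aic = ft$aic, ks = ks)
  }
  if (!length(rows)) .stopf("no candidate family could be fitted")
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$pars <- I(lapply(fits[out$family], function(f) f$estimate))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares squared correlations with squared anti-image partial correlations
#' derived from the inverse correlation matrix:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal pairs,
#' with the per-variable analogue computed row-wise.
#'
#' @param R invertible correlation matrix (p >= 2) that is not the identity.
#' @return List with `overall` and named `per_variable` KMO values.
#' @export
kmo_statistic <- function(R) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (p < 2L || ncol(R) != p) .stopf("domain error: need a square correlation matrix, p >= 2")
  Rinv <- tryCatch(solve(R), error = function(e)
    .stopf("domain error: correlation matrix is singular"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)       # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  if (sum(r2) < 1e-12)
    .stopf("domain error: correlation matrix is the identity; KMO undefined")
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_var <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_var) <- rownames(R)
  list(overall = overall, per_variable = per_var)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity using
#' `-(n - 1 - (2p + 5)/6) * log det(R)` against chi-square with
#' `p(p-1)/2` degrees of freedom.
#'
#' @param R positive-definite correlation matrix.
#' @param n sample size the correlations were computed from (n > p).
#' @return A test result with `statistic`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- nrow(R)
  ch <- tryCatch(chol(R), error = function(e)
    .stopf("domain error: correlation matrix must be positive definite"))
  if (n <= p) .stopf("domain error: need n > p")
  ldet <- 2 * sum(log(diag(ch)))
  stat <- -(n - 1 - (2 * p + 5) / 6) * ldet
  df <- p * (p - 1) / 2
  .test_result(stat, as.integer(df), stats::pchisq(stat, df, lower.tail = FALSE),
               "Bartlett sphericity")
}

#' Exploratory factor loadings by principal-axis factoring
#'
#' Iterative principal-axis extraction (squared multiple correlations as
#' starting communalities) followed by varimax rotation when more than one
#' factor is requested.
#'
#' @param R correlation matrix.
#' @param n_factors number of factors, strictly less than p.
#' @param max_iter,tol iteration controls for the communality loop.
#' @return List with `loadings` (p x n_factors) and `communalities`.
#' @export
extract_factor_loadings <- function(R, n_factors, max_iter = 100, tol = 1e-6) {
  R <- as.matrix(R)
  p <- nrow(R)
  if (n_factors >= p) .stopf("domain error: n_factors must be smaller than the number of variables")
  if (n_factors < 1L) .stopf("domain error: need at least one factor")
  h <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  h <- pmin(pmax(h, 0), 0.999)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(ev), n_factors)
    h_new <- pmin(rowSums(L^2), 0.999)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  if (n_factors > 1L && max(abs(L)) > 1e-8) {
    rot <- tryCatch(stats::varimax(L), error = function(e) NULL)
    if (!is.null(rot)) L <- unclass(rot$loadings)
  }
  dimnames(L) <- list(rownames(R), paste0("F", seq_len(n_factors)))
  list(loadings = L, communalities = stats::setNames(rowSums(L^2), rownames(R)))
}
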