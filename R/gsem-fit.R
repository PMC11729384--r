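# Maximum-likelihood fitting of the joint GSEM by quasi-Newton (BFGS) with
# analytic gradients, plus model-based (inverse observed information) and
# robust sandwich covariance, and the usual S3 modelling methods.

#' Optimizer and numerical controls for [fit_gsem()]
#'
#' @param maxit maximum BFGS warm-up iterations. The heavy lifting is done
#'   by the BHHH Newton loop (see `polish`), the standard technique for
#'   latent-variable likelihoods; a short quasi-Newton warm-up merely moves
#'   the start into the right basin.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @param gtol gradient tolerance: the fit is flagged converged when the
#'   largest (parameter-scaled) gradient entry is below
#'   `gtol * max(1, |loglik|)`.
#' @param prefit fit each latent's measurement sub-model first and use its
#'   estimates as start values for the joint fit (recommended for the full
#'   model; ignored for specs without both latents and a disease model).
#' @param prefit_n prefits run on at most this many records (the leading
#'   rows); start values do not need full-sample precision.
#' @param polish after BFGS, take safeguarded Newton steps using the
#'   outer-product-of-scores (BHHH) curvature until the gradient is
#'   negligible (`NULL` = on). Quasi-Newton alone creeps along the curved
#'   loading/latent-SD ridge of strong-loading measurement models; the
#'   polish resolves it.
#' @param polish_maxit maximum polish steps.
#' @param newton_maxit,newton_tol damped-Newton controls for the per-person
#'   posterior-mode search inside the adaptive quadrature.
#' @param sharp,eps smooth-cap parameters keeping the log-link probability
#'   strictly below 1: the linear predictor is softly capped at `-eps` with
#'   sharpness `sharp`.
#' @param trace print optimizer progress (0 = silent).
#' @return List of controls.
#' @export
gsem_control <- function(maxit = 25L, reltol = 1e-10, gtol = 1e-5,
                         prefit = TRUE, prefit_n = 6000L,
                         polish = NULL, polish_maxit = 150L,
                         newton_maxit = 60L, newton_tol = 1e-10,
                         sharp = 0.01, eps = 1e-8, trace = 0L) {
  list(maxit = as.integer(maxit), reltol = reltol, gtol = gtol,
       prefit = isTRUE(prefit), prefit_n = as.integer(prefit_n),
       polish = polish,
       polish_maxit = as.integer(polish_maxit),
       newton_maxit = as.integer(newton_maxit), newton_tol = newton_tol,
       sharp = sharp, eps = eps, trace = as.integer(trace))
}

# Parameter scales for optim's parscale: roughly the expected magnitude of
# each coefficient, so that coefficients of large-scale covariates (kcal/day,
# minutes/week) do not slow the quasi-Newton search.
.parscale <- function(model, start) {
  ps <- pmax(abs(start), 1)
  map <- model$map
  scale_for <- function(M) {
    sds <- apply(M, 2, stats::sd)
    ifelse(sds > 1e-12, pmin(1 / sds, 1), 1)
  }
  if (length(map$beta_x))
    ps[map$beta_x] <- pmax(abs(start[map$beta_x]), scale_for(model$X))
  if (!is.null(map$gamma)) {
    sc <- scale_for(model$S)
    for (d in seq_len(nrow(map$gamma)))
      ps[map$gamma[d, ]] <- pmax(abs(start[map$gamma[d, ]]), sc)
  }
  unname(ps)
}

#' Fit a generalized structural equation model by maximum likelihood
#'
#' Maximizes the joint likelihood of the Weibull measurement models, the
#' structural latent regressions and the log-link Bernoulli disease model,
#' integrating over the latent dimensions with adaptive Gauss-Hermite
#' quadrature. Optimization is quasi-Newton (BFGS) with analytic gradients
#' from a deterministic start ([gsem_start()]). The model-based covariance is
#' the inverse observed information (finite differences of the analytic
#' gradient); the robust covariance is the sandwich
#' \eqn{A^{-1} B A^{-1}} with \eqn{B = \sum_i w_i^2 s_i s_i'} built from
#' per-person scores, the "modified Poisson" variance estimator for the
#' prevalence-ratio scale.
#'
#' @param spec a [gsem_spec()].
#' @param data person-level data frame with all columns named in the spec.
#' @param quad quadrature nodes per latent dimension; the default (`NULL`)
#'   uses 41 nodes for single-latent models and 13 per dimension for
#'   two-latent models, counts at which the quadrature error of the
#'   log-likelihood is negligible even under strong loadings (the skewed
#'   Weibull kernel needs more than the customary handful of nodes).
#' @param start optional named start vector (packing order of [gsem_start()]).
#' @param se compute the model-based and robust covariance matrices
#'   (set `FALSE` to save time when only point estimates are needed).
#' @param control a [gsem_control()] list.
#' @return An object of class `gsem_fit` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `nobs`, `confint`, `predict`, `simulate`,
#'   `residuals` and `plot`.
#' @export
fit_gsem <- function(spec, data, quad = NULL, start = NULL, se = TRUE,
                     control = gsem_control()) {
  cl <- match.call()
  model <- .prepare_model(spec, data)
  if (model$n < model$P)
    .stopf("need at least as many records (%d) as free parameters (%d)", model$n, model$P)
  if (is.null(quad)) quad <- if (model$D >= 2L) 13L else 41L
  if (quad < 3) .stopf("quadrature needs at least 3 nodes per dimension")
  quad <- as.integer(quad)

  th0 <- if (is.null(start)) .gsem_start(model) else {
    if (length(start) != model$P)
      .stopf("start has length %d, expected %d", length(start), model$P)
    stats::setNames(as.numeric(start), model$par_names)
  }

  # Measurement prefits: fit each latent's indicators alone (1-D quadrature)
  # and seed the joint start with the resulting measurement parameters.
  if (is.null(start) && control$prefit && model$D >= 1L && !is.null(model$X)) {
    pre_data <- as.data.frame(data)
    if (nrow(pre_data) > control$prefit_n)
      pre_data <- pre_data[seq_len(control$prefit_n), , drop = FALSE]
    for (d in seq_len(model$D)) {
      sub <- gsem_spec(latents = model$spec$latents[d],
                       structural = model$spec$structural,
                       reference = stats::setNames(model$spec$reference[d],
                                                   model$lat_names[d]),
                       weights = model$spec$weights)
      subfit <- tryCatch(
        fit_gsem(sub, pre_data, quad = NULL, se = FALSE,
                 control = gsem_control(prefit = FALSE, trace = 0L)),
        error = function(e) NULL)
      if (!is.null(subfit) && all(is.finite(subfit$coefficients)) &&
          subfit$converged) {
        sm <- subfit$internal$map
        if (!is.null(model$map$gamma))
          th0[model$map$gamma[d, ]] <- subfit$coefficients[sm$gamma[1, ]]
        th0[model$map$kappa[[d]]] <- subfit$coefficients[sm$kappa[[1]]]
        th0[model$map$lambda[[d]]] <- subfit$coefficients[sm$lambda[[1]]]
        th0[model$map$logshape[[d]]] <- subfit$coefficients[sm$logshape[[1]]]
        lsd <- subfit$coefficients[sm$psi]
        if (model$D == 1L) th0[model$map$psi] <- lsd
        else th0[model$map$psi[if (d == 1L) 1L else 3L]] <- lsd
      }
    }
  }

  menv <- new.env(parent = emptyenv())
  menv$modes <- NULL
  menv$theta <- NULL
  menv$ev <- NULL
  menv$count <- 0L
  menv$best_ll <- -Inf
  evalfn <- function(th, need_score = TRUE) {
    if (!is.null(menv$theta) && identical(th, menv$theta) &&
        (!need_score || !is.null(menv$ev$score))) return(menv$ev)
    ev <- .gsem_eval(th, model, quad = quad, score = need_score,
                     modes = menv$modes, sharp = control$sharp,
                     eps = control$eps, newton_maxit = control$newton_maxit,
                     newton_tol = control$newton_tol)
    menv$count <- menv$count + 1L
    # warm-start posterior modes only from evaluations in the same basin as
    # the best seen; a rejected wild candidate must not poison later calls
    if (is.finite(ev$loglik) && ev$loglik > menv$best_ll - 1e3) {
      menv$modes <- ev$modes
      menv$best_ll <- max(menv$best_ll, ev$loglik)
    }
    menv$theta <- th
    menv$ev <- ev
    ev
  }
  fn <- function(th) {
    ev <- evalfn(th, need_score = FALSE)   # line-search probes skip scores
    if (!is.finite(ev$loglik)) 1e10 else -ev$loglik
  }
  gr <- function(th) {
    ev <- evalfn(th)
    if (!is.finite(ev$loglik) || any(!is.finite(ev$gradient))) rep(0, model$P)
    else -ev$gradient
  }

  ps <- .parscale(model, th0)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = control$maxit, reltol = control$reltol,
                                     parscale = ps, trace = control$trace))
  theta <- opt$par

  # Newton polish: BFGS alone creeps along the curved lambda/sigma ridge of
  # strong-loading measurement models; safeguarded Newton steps resolve it.
  # The curvature matrix is the outer product of per-person scores (BHHH),
  # which equals the information at the optimum and costs nothing extra.
  polish <- control$polish
  if (is.null(polish)) polish <- TRUE
  polish_stalled <- FALSE
  # latent-free evaluations are cheap and exact, so polish those to machine
  # precision (the GLM-equivalence contract); quadrature surfaces stop at
  # their numerical floor
  p_gtol <- if (model$D == 0L) 1e-13 else 1e-8
  if (isTRUE(polish)) {
    for (np in seq_len(control$polish_maxit)) {
      ev <- evalfn(theta)
      if (!is.finite(ev$loglik)) break
      gvec <- ev$gradient
      if (max(abs(gvec * ps)) < p_gtol * max(1, abs(ev$loglik))) break
      H <- crossprod(ev$score * sqrt(model$w))
      Dg <- pmax(abs(diag(H)), 1e-8)
      improved <- FALSE
      for (tau in c(0, 1e-4, 1e-2, 1, 100)) {
        step <- tryCatch(solve(H + tau * diag(Dg, model$P), gvec),
                         error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) next
        fac <- 1
        for (hv in 1:10) {
          cand <- theta + fac * step
          if (fn(cand) < -ev$loglik - 1e-10) { improved <- TRUE; break }
          fac <- fac / 2
        }
        if (improved) break
      }
      if (!improved) { polish_stalled <- TRUE; break }
      gain <- -fn(cand) - ev$loglik
      theta <- cand
      if (gain < p_gtol * max(1, abs(ev$loglik))) { polish_stalled <- TRUE; break }
    }
    # The log-link Bernoulli likelihood is concave, so for latent-free models
    # finish with pure Newton steps judged on the gradient norm: likelihood
    # gains near the optimum fall below summation noise long before the
    # gradient does, and the GLM-equivalence contract needs the exact root.
    if (model$D == 0L) {
      for (np in seq_len(10L)) {
        ev <- evalfn(theta)
        gvec <- ev$gradient
        if (!all(is.finite(gvec))) break
        gn0 <- max(abs(gvec * ps))
        if (gn0 < 1e-11 * max(1, abs(ev$loglik))) break
        H <- crossprod(ev$score * sqrt(model$w))
        step <- tryCatch(solve(H, gvec), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        cand <- theta + step
        evc <- evalfn(cand)
        if (!is.finite(evc$loglik) || !all(is.finite(evc$gradient)) ||
            max(abs(evc$gradient * ps)) >= gn0) break
        theta <- cand
      }
    }
  }

  ev <- evalfn(theta)
  loglik <- ev$loglik
  grad <- ev$gradient
  gmax <- if (all(is.finite(grad))) max(abs(grad * ps)) else Inf
  # converged: either the scaled gradient is below tolerance, or the Newton
  # polish stalled at a point where no regularised ascent step improves the
  # likelihood (a local maximum at the resolution of the quadrature surface)
  converged <- is.finite(loglik) && is.finite(gmax) &&
    (gmax < control$gtol * max(1, abs(loglik)) ||
       (polish_stalled && opt$convergence %in% c(0L, 1L)))

  fit <- structure(list(
    spec = spec, coefficients = stats::setNames(theta, model$par_names),
    loglik = loglik, n = model$n, sum_w = sum(model$w),
    converged = converged, optim_convergence = opt$convergence,
    iterations = opt$counts, grad_max = gmax,
    quad = quad, control = control, start = th0,
    model_vcov = NULL, robust_vcov = NULL,
    internal = model, modes = ev$modes, call = cl), class = "gsem_fit")

  if (se) {
    fit <- .add_vcov(fit)
  }
  fit
}

# Observed-information and sandwich covariance at the estimate.
.add_vcov <- function(fit) {
  model <- fit$internal
  control <- fit$control
  menv <- new.env(parent = emptyenv()); menv$modes <- fit$modes
  gfun <- function(t) {
    e <- .gsem_eval(t, model, quad = fit$quad, score = TRUE, modes = menv$modes,
                    sharp = control$sharp, eps = control$eps,
                    newton_maxit = control$newton_maxit,
                    newton_tol = control$newton_tol)
    if (is.finite(e$loglik)) menv$modes <- e$modes
    -e$gradient
  }
  A <- .num_hessian(gfun, fit$coefficients)   # observed information
  Vm <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Vm)) {
    bad <- model$par_names[abs(diag(A)) < 1e-8 * max(abs(diag(A)), 1)]
    .stopf("singular information matrix; parameters involved: %s",
           paste(if (length(bad)) bad else model$par_names, collapse = ", "))
  }
  Vm <- (Vm + t(Vm)) / 2
  dimnames(Vm) <- list(model$par_names, model$par_names)
  ev <- .gsem_eval(fit$coefficients, model, quad = fit$quad, score = TRUE,
                   modes = fit$modes, sharp = control$sharp, eps = control$eps)
  B <- crossprod(ev$score * model$w)
  Vr <- Vm %*% B %*% Vm
  Vr <- (Vr + t(Vr)) / 2
  dimnames(Vr) <- dimnames(Vm)
  fit$model_vcov <- Vm
  fit$robust_vcov <- Vr
  fit
}

#' Robust (sandwich) covariance of a fitted GSEM
#'
#' Returns the modified-Poisson-style sandwich covariance
#' \eqn{A^{-1} B A^{-1}}, computing it (together with the model-based
#' covariance) if the fit was produced with `se = FALSE`.
#'
#' @param fitted a converged [fit_gsem()] object.
#' @return Covariance matrix over the free parameters.
#' @export
robust_vcov <- function(fitted) {
  if (!inherits(fitted, "gsem_fit")) .stopf("'fitted' must be a gsem_fit")
  if (!isTRUE(fitted$converged))
    .stopf("precondition error: robust variance requires a converged fit")
  if (is.null(fitted$robust_vcov)) fitted <- .add_vcov(fitted)
  fitted$robust_vcov
}

#' Akaike and Bayesian information criteria of a fitted GSEM
#'
#' `AIC = 2k - 2logLik`, `BIC = k log(n) - 2logLik` with `k` free parameters
#' and `n` persons.
#'
#' @param fitted a [fit_gsem()] object with a finite log-likelihood.
#' @return Named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fitted) {
  if (!inherits(fitted, "gsem_fit") || is.null(fitted$loglik) || !is.finite(fitted$loglik))
    .stopf("precondition error: fitted model with a finite log-likelihood required")
  k <- length(fitted$coefficients)
  c(AIC = 2 * k - 2 * fitted$loglik,
    BIC = k * log(fitted$n) - 2 * fitted$loglik)
}

#' @export
logLik.gsem_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.gsem_fit <- function(object, ...) object$n

#' @export
coef.gsem_fit <- function(object, ...) object$coefficients

#' @export
vcov.gsem_fit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  V <- if (type == "robust") object$robust_vcov else object$model_vcov
  if (is.null(V)) {
    object <- .add_vcov(object)
    V <- if (type == "robust") object$robust_vcov else object$model_vcov
  }
  V
}

#' @export
confint.gsem_fit <- function(object, parm, level = 0.95,
                             type = c("robust", "model"), ...) {
  type <- match.arg(type)
  V <- vcov(object, type = type)
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  rownames(ci) <- names(object$coefficients)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.gsem_fit <- function(x, ...) {
  cat("Generalized structural equation model (Weibull indicators, log-link disease model)\n")
  cat(sprintf("  %d persons, %d free parameters, %d-node adaptive quadrature per dimension\n",
              x$n, length(x$coefficients), x$quad))
  cat(sprintf("  logLik %.2f | AIC %.1f | BIC %.1f | %s\n",
              x$loglik, information_criteria(x)["AIC"], information_criteria(x)["BIC"],
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$internal$map$beta_L)) {
    pr <- exp(x$coefficients[x$internal$map$beta_L])
    cat("  latent prevalence ratios:",
        paste(sprintf("%s %.3f", x$internal$lat_names, pr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.gsem_fit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  V <- vcov(object, type = type)
  Vm <- vcov(object, type = "model")
  se <- sqrt(pmax(diag(V), 0))
  sem <- sqrt(pmax(diag(Vm), 0))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `SE (model)` = sem,
               `SE (robust)` = se, z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 ic = information_criteria(object), n = object$n,
                 converged = object$converged, grad_max = object$grad_max,
                 type = type, lat_names = object$internal$lat_names),
            class = "summary.gsem_fit")
}

#' @export
print.summary.gsem_fit <- function(x, ...) {
  cat(sprintf("GSEM fit: n = %d, logLik = %.2f, AIC = %.1f, BIC = %.1f (%s, max scaled gradient %.2e)\n\n",
              x$n, x$loglik, x$ic["AIC"], x$ic["BIC"],
              if (x$converged) "converged" else "NOT converged", x$grad_max))
  stats::printCoefmat(x$coefficients, digits = 4, signif.stars = FALSE)
  invisible(x)
}

#' @export
predict.gsem_fit <- function(object, newdata = NULL,
                             type = c("scores", "link", "response"), ...) {
  type <- match.arg(type)
  if (type == "scores") return(eb_scores(object, newdata = newdata, ...))
  model <- if (is.null(newdata)) object$internal else .prepare_model(object$spec, newdata)
  if (is.null(model$X)) .stopf("spec has no disease model")
  pp <- .unpack(object$coefficients, model)
  eta <- drop(model$X %*% pp$beta_x)
  if (model$D > 0L) {
    sc <- eb_scores(object, newdata = newdata)
    for (d in seq_len(model$D))
      eta <- eta + pp$beta_L[d] * sc[[paste0(model$lat_names[d], "_mean")]]
  }
  if (type == "link") eta else exp(.softcap(eta)$h)
}

#' @export
residuals.gsem_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(object$internal$X)) .stopf("spec has no disease model")
  pi_hat <- predict(object, type = "response")
  r <- object$internal$y - pi_hat
  if (type == "pearson") r / sqrt(pmax(pi_hat * (1 - pi_hat), 1e-12)) else r
}

#' Simulate datasets from a fitted GSEM
#'
#' Draws new latent values, indicator times and (when the spec has a disease
#' model) outcomes from the fitted parameters, keeping the observed
#' covariates fixed — the parametric-bootstrap data-generating step.
#'
#' @param object a fitted model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` data frames.
#' @export
simulate.gsem_fit <- function(object, nsim = 1, seed = NULL, ...) {
  model <- object$internal
  pp <- .unpack(object$coefficients, model)
  one <- function() {
    n <- model$n; D <- model$D
    mu <- if (is.null(model$S)) matrix(0, n, max(D, 1)) else model$S %*% t(pp$Gamma)
    out <- list()
    L <- NULL
    if (D > 0L) {
      Z <- matrix(stats::rnorm(n * D), n, D)
      L <- mu + Z %*% t(pp$psi$C)
      for (d in seq_len(D)) {
        for (j in seq_len(model$ind[[d]]$p)) {
          nmj <- model$ind[[d]]$names[j]
          out[[nmj]] <- sample_weibull_indicator(L[, d], pp$lambda[[d]][j],
                                                 pp$kappa[[d]][j], pp$shape[[d]][j])
        }
      }
    }
    if (!is.null(model$X)) {
      eta <- drop(model$X %*% pp$beta_x)
      if (D > 0L) for (d in seq_len(D)) eta <- eta + pp$beta_L[d] * L[, d]
      out[[all.vars(object$spec$disease)[1]]] <- as.integer(sample_obesity(eta))
    }
    as.data.frame(out)
  }
  runner <- function() replicate(nsim, one(), simplify = FALSE)
  if (is.null(seed)) runner() else withr::with_seed(seed, runner())
}

#' @export
plot.gsem_fit <- function(x, ...) {
  model <- x$internal
  op <- graphics::par(mfrow = c(1, max(model$D, 1)), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  if (model$D == 0L) {
    pr <- exp(x$coefficients[model$map$beta_x])
    graphics::barplot(pr, las = 2, ylab = "prevalence ratio",
                      main = "Disease-model PRs")
    graphics::abline(h = 1, lty = 2)
    return(invisible(x))
  }
  for (d in seq_len(model$D)) {
    lam <- rep(1, model$ind[[d]]$p)
    lam[model$map$lambda_pos[[d]]] <- x$coefficients[model$map$lambda[[d]]]
    names(lam) <- model$ind[[d]]$names
    graphics::barplot(lam, las = 2, ylab = "loading (ref = 1)",
                      main = sprintf("Latent '%s'", model$lat_names[d]))
    graphics::abline(h = 0)
  }
  invisible(x)
}
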