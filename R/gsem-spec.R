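# Declarative model specification for the joint GSEM: latent dimensions with
# Weibull indicator measurement models, optional structural paths from
# observed covariates to the latents, and an optional log-link Bernoulli
# disease model. Also hosts the fixed parameter-packing order and the
# deterministic start-value construction.

#' Specify a generalized structural equation model
#'
#' Declares the model structure fitted by [fit_gsem()]: one or two latent
#' dimensions, each measured by named Weibull indicators with the first (or a
#' chosen) indicator as the reference whose loading is fixed at 1; optional
#' structural regressions of every latent on observed covariates; and an
#' optional disease model, a log-link Bernoulli regression of a binary
#' outcome on observed covariates in which all latents enter as additional
#' terms. Any of the three blocks may be dropped: a spec with latents and no
#' disease model is a pure measurement model; a spec with `latents = NULL`
#' and a disease formula is the latent-free ("modified Poisson") regression.
#'
#' @param latents named list of character vectors of indicator column names,
#'   e.g. `list(screens = c("computer_smartphone", "tv", "video_games"))`, or
#'   `NULL` for a latent-free model.
#' @param disease two-sided formula for the disease model, e.g.
#'   `obesity ~ sex + age`; the outcome must be binary 0/1. `NULL` drops the
#'   disease model.
#' @param structural one-sided formula of covariates with paths into every
#'   latent, e.g. `~ leisure_pa`. No intercept is used (latent location is
#'   carried by the indicator intercepts). `NULL` drops the paths.
#' @param reference optional named character vector choosing the reference
#'   indicator per latent (default: the first listed indicator).
#' @param weights optional name of a positive per-person weight (expansion
#'   factor) column; weights multiply the per-person log-likelihood
#'   contributions.
#' @return An object of class `gsem_spec`.
#' @examples
#' gsem_spec(
#'   latents = list(screens = c("computer_smartphone", "tv", "video_games"),
#'                  transport = c("motor_vehicle", "cycling", "walking")),
#'   disease = obesity ~ sex + age + ethnicity + schooling + wealth_quartile +
#'     energy_kcal + leisure_pa,
#'   structural = ~ leisure_pa)
#' @export
gsem_spec <- function(latents = NULL, disease = NULL, structural = NULL,
                      reference = NULL, weights = NULL) {
  if (!is.null(latents)) {
    if (!is.list(latents) || is.null(names(latents)) || any(names(latents) == ""))
      .stopf("'latents' must be a named list of indicator name vectors")
    all_ind <- unlist(latents)
    if (anyDuplicated(all_ind))
      .stopf("each indicator may belong to exactly one latent")
    if (any(lengths(latents) < 1L)) .stopf("every latent needs at least one indicator")
    if (length(latents) > 2L)
      .stopf("at most two latent dimensions are supported")
  }
  ref <- lapply(seq_along(latents), function(d) {
    nm <- names(latents)[d]
    r <- if (!is.null(reference) && nm %in% names(reference)) reference[[nm]] else latents[[d]][1]
    if (!r %in% latents[[d]])
      .stopf("reference indicator '%s' is not an indicator of latent '%s'", r, nm)
    r
  })
  names(ref) <- names(latents)
  if (!is.null(disease) && !inherits(disease, "formula"))
    .stopf("'disease' must be a formula or NULL")
  if (!is.null(structural)) {
    if (!inherits(structural, "formula") || length(structural) != 2L)
      .stopf("'structural' must be a one-sided formula or NULL")
    if (is.null(latents)) .stopf("structural paths need at least one latent")
  }
  if (is.null(latents) && is.null(disease))
    .stopf("the model needs at least a measurement or a disease block")
  structure(list(latents = latents, disease = disease, structural = structural,
                 reference = ref, weights = weights),
            class = "gsem_spec")
}

#' @export
print.gsem_spec <- function(x, ...) {
  cat("GSEM specification\n")
  if (length(x$latents)) {
    for (d in names(x$latents)) {
      cat(sprintf("  latent '%s': %s (reference: %s)\n", d,
                  paste(x$latents[[d]], collapse = ", "), x$reference[[d]]))
    }
  } else cat("  no latent dimensions (latent-free model)\n")
  if (!is.null(x$structural))
    cat("  structural paths:", deparse(x$structural), "on every latent\n")
  if (!is.null(x$disease))
    cat("  disease model (log-link Bernoulli):", deparse(x$disease), "+ latents\n")
  if (!is.null(x$weights)) cat("  weights column:", x$weights, "\n")
  invisible(x)
}

# Build the internal model representation: data matrices, parameter map and
# names. The packing order is fixed and documented:
#   for each latent d (spec order):
#     kappa (all indicators), lambda (non-reference indicators), log-shape
#     (all indicators);
#   then structural coefficients gamma (latent-major, covariate-minor);
#   then the latent residual covariance (log-Cholesky: log sd for one latent;
#   log c11, c21, log c22 for two);
#   then disease coefficients (model-matrix columns, then one coefficient per
#   latent).
.prepare_model <- function(spec, data) {
  if (!inherits(spec, "gsem_spec")) .stopf("'spec' must be a gsem_spec")
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n == 0L) .stopf("empty dataset")
  D <- length(spec$latents)
  lat_names <- names(spec$latents)

  ind <- vector("list", D)
  par_names <- character(0)
  map <- list(kappa = vector("list", D), lambda = vector("list", D),
              lambda_pos = vector("list", D), logshape = vector("list", D))
  idx <- 0L
  for (d in seq_len(D)) {
    nm <- spec$latents[[d]]
    miss <- setdiff(nm, names(data))
    if (length(miss))
      .stopf("data is missing indicator columns: %s", paste(miss, collapse = ", "))
    T <- as.matrix(data[nm]); storage.mode(T) <- "double"
    if (any(!is.finite(T)) || any(T <= 0))
      .stopf("indicator times must be finite and strictly positive (records with missing indicators are not allowed; shift zeros before fitting)")
    p_d <- length(nm)
    refj <- match(spec$reference[[d]], nm)
    ind[[d]] <- list(names = nm, ref = refj, T = T, logT = log(T), p = p_d)
    map$kappa[[d]] <- idx + seq_len(p_d); idx <- idx + p_d
    par_names <- c(par_names, paste0(lat_names[d], ".kappa.", nm))
    free <- setdiff(seq_len(p_d), refj)
    map$lambda_pos[[d]] <- free
    map$lambda[[d]] <- if (length(free)) idx + seq_along(free) else integer(0)
    idx <- idx + length(free)
    par_names <- c(par_names, paste0(lat_names[d], ".lambda.", nm[free]))
    map$logshape[[d]] <- idx + seq_len(p_d); idx <- idx + p_d
    par_names <- c(par_names, paste0(lat_names[d], ".logshape.", nm))
  }

  S <- NULL; s_names <- character(0)
  if (!is.null(spec$structural)) {
    S <- stats::model.matrix(spec$structural, data)
    keep <- colnames(S) != "(Intercept)"
    S <- S[, keep, drop = FALSE]
    if (ncol(S) == 0L) .stopf("structural formula has no covariates")
    s_names <- colnames(S)
    map$gamma <- matrix(0L, D, ncol(S))
    for (d in seq_len(D)) {
      map$gamma[d, ] <- idx + seq_len(ncol(S)); idx <- idx + ncol(S)
      par_names <- c(par_names, paste0("gamma.", lat_names[d], ".", s_names))
    }
  } else map$gamma <- NULL

  if (D == 1L) {
    map$psi <- idx + 1L; idx <- idx + 1L
    par_names <- c(par_names, paste0("psi.logsd.", lat_names[1]))
  } else if (D == 2L) {
    map$psi <- idx + 1:3; idx <- idx + 3L
    par_names <- c(par_names,
                   paste0("psi.logchol.", lat_names[1]),
                   paste0("psi.chol.", lat_names[2], ".", lat_names[1]),
                   paste0("psi.logchol.", lat_names[2]))
  } else map$psi <- integer(0)

  X <- NULL; y <- NULL; x_names <- character(0)
  if (!is.null(spec$disease)) {
    mf <- stats::model.frame(spec$disease, data, na.action = stats::na.fail)
    y <- stats::model.response(mf)
    if (!all(y %in% c(0, 1))) .stopf("disease outcome must be binary 0/1")
    y <- as.numeric(y)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    x_names <- colnames(X)
    map$beta_x <- idx + seq_len(ncol(X)); idx <- idx + ncol(X)
    par_names <- c(par_names, paste0("disease.", x_names))
    if (D > 0L) {
      map$beta_L <- idx + seq_len(D); idx <- idx + D
      par_names <- c(par_names, paste0("disease.L.", lat_names))
    } else map$beta_L <- integer(0)
  } else {
    map$beta_x <- integer(0); map$beta_L <- integer(0)
  }

  w <- rep(1, n)
  if (!is.null(spec$weights)) {
    if (!spec$weights %in% names(data)) .stopf("weight column '%s' not found", spec$weights)
    w <- as.numeric(data[[spec$weights]])
    if (any(!is.finite(w)) || any(w <= 0)) .stopf("weights must be finite and positive")
  }

  list(spec = spec, n = n, D = D, lat_names = lat_names, ind = ind,
       S = S, s_names = s_names, X = X, y = y, x_names = x_names,
       w = w, map = map, P = idx, par_names = par_names)
}

# Unpack a parameter vector into model quantities.
.unpack <- function(theta, model) {
  map <- model$map
  D <- model$D
  kappa <- lambda <- shape <- vector("list", D)
  for (d in seq_len(D)) {
    p_d <- model$ind[[d]]$p
    kappa[[d]] <- theta[map$kappa[[d]]]
    lam <- rep(1, p_d)
    lam[map$lambda_pos[[d]]] <- theta[map$lambda[[d]]]
    lambda[[d]] <- lam
    shape[[d]] <- exp(theta[map$logshape[[d]]])
  }
  Gamma <- NULL
  if (!is.null(map$gamma)) {
    Gamma <- matrix(theta[t(map$gamma)], nrow = D, byrow = TRUE)
  }
  psi <- NULL
  if (D == 1L) {
    sig <- exp(theta[map$psi])
    psi <- list(C = matrix(sig), Psi = matrix(sig^2),
                Psi_inv = matrix(1 / sig^2), ldetC = log(sig), sd = sig)
  } else if (D == 2L) {
    l1 <- theta[map$psi[1]]; c21 <- theta[map$psi[2]]; l2 <- theta[map$psi[3]]
    C <- matrix(c(exp(l1), c21, 0, exp(l2)), 2, 2)
    Psi <- C %*% t(C)
    # invert via the triangular factor (stable for any admissible parameters)
    Cinv <- matrix(c(exp(-l1), -c21 * exp(-l1 - l2), 0, exp(-l2)), 2, 2)
    psi <- list(C = C, Psi = Psi, Psi_inv = crossprod(Cinv),
                ldetC = l1 + l2, sd = sqrt(diag(Psi)), chol_pars = c(l1, c21, l2))
  }
  beta_x <- theta[map$beta_x]
  beta_L <- theta[map$beta_L]
  list(kappa = kappa, lambda = lambda, shape = shape, Gamma = Gamma,
       psi = psi, beta_x = beta_x, beta_L = beta_L)
}

# Deterministic start values: marginal Weibull fits for intercepts/shapes,
# method-of-moments loadings and latent SD from log-time covariance triples,
# zero structural paths and latent correlation, disease coefficients from a
# latent-free Poisson-family log-link fit, zero latent disease coefficients.
.gsem_start <- function(model) {
  theta <- numeric(model$P)
  map <- model$map
  for (d in seq_len(model$D)) {
    lt <- model$ind[[d]]$logT
    p_d <- model$ind[[d]]$p
    refj <- model$ind[[d]]$ref
    kap0 <- numeric(p_d); k0 <- numeric(p_d)
    for (j in seq_len(p_d)) {
      t_j <- model$ind[[d]]$T[, j]
      fit <- tryCatch(survival::survreg(survival::Surv(t_j, rep(1, length(t_j))) ~ 1,
                                        dist = "weibull"),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$coefficients[1]) || !is.finite(fit$scale)) {
        kap0[j] <- log(stats::median(t_j)) + 0.3
        k0[j] <- 1.2
      } else {
        kap0[j] <- unname(fit$coefficients[1])
        k0[j] <- max(min(1 / fit$scale, 50), 0.05)
      }
    }
    theta[map$kappa[[d]]] <- kap0
    theta[map$logshape[[d]]] <- log(k0)
    # latent variance and loadings via covariance triples around the reference
    V <- stats::cov(lt)
    free <- map$lambda_pos[[d]]
    sig2 <- NA_real_
    if (p_d >= 3L) {
      oth <- setdiff(seq_len(p_d), refj)
      a <- oth[1]; b <- oth[2]
      if (abs(V[a, b]) > 1e-8) sig2 <- V[refj, a] * V[refj, b] / V[a, b]
    }
    if (!is.finite(sig2) || sig2 <= 1e-6)
      sig2 <- max(0.05 * V[refj, refj], 1e-4)
    lam0 <- V[refj, free] / sig2
    lam0[!is.finite(lam0)] <- 0
    deg <- abs(lam0) < 1e-3 | abs(lam0) > 100
    if (any(deg)) {
      sgn <- sign(V[refj, free[deg]]); sgn[sgn == 0] <- 1
      lam0[deg] <- 0.1 * sgn
    }
    theta[map$lambda[[d]]] <- lam0
    if (model$D == 1L) {
      theta[map$psi] <- 0.5 * log(sig2)
    } else {
      theta[map$psi[if (d == 1L) 1L else 3L]] <- 0.5 * log(sig2)
    }
  }
  if (!is.null(map$gamma)) theta[map$gamma] <- 0
  if (length(map$beta_x)) {
    g0 <- tryCatch(
      stats::glm.fit(model$X, model$y, family = stats::poisson(link = "log"))$coefficients,
      error = function(e) NULL)
    if (is.null(g0)) {
      g0 <- numeric(ncol(model$X))
      if ("(Intercept)" %in% model$x_names)
        g0[match("(Intercept)", model$x_names)] <- log(max(mean(model$y), 1e-3))
    }
    g0[!is.finite(g0)] <- 0
    theta[map$beta_x] <- g0
  }
  if (length(map$beta_L)) theta[map$beta_L] <- 0
  names(theta) <- model$par_names
  theta
}

#' Deterministic start values for a GSEM fit
#'
#' Exposes the start-value construction used by [fit_gsem()]: marginal
#' Weibull fits give indicator intercepts and shapes, log-time covariance
#' triples give method-of-moments loadings and latent SDs, and a latent-free
#' Poisson-family log-link fit gives the disease coefficients. Useful for
#' inspecting or perturbing the optimizer's starting point and for building
#' parameter vectors in the documented packing order (see the names of the
#' returned vector).
#'
#' @param spec a [gsem_spec()].
#' @param data person-level data frame.
#' @return Named numeric vector of start values in packing order.
#' @export
gsem_start <- function(spec, data) {
  .gsem_start(.prepare_model(spec, data))
}
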