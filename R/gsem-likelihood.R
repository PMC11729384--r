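# Joint log-likelihood of the GSEM, integrated over the latent dimensions by
# adaptive Gauss-Hermite quadrature (mode- and curvature-rescaled nodes),
# with analytic per-person scores via the Fisher identity: the score of an
# integrated log-likelihood is the posterior expectation of the
# complete-data score, approximated on the same quadrature grid.
#
# Per person the integrand is
#   prod_j Weibull(t_j; k_j, exp(kappa_j + lambda_j L_d(j)))
#   * Bernoulli(y; pi = exp(softcap(eta)))   [eta = x'beta + sum_d betaL_d L_d]
#   * N(L; Gamma s_i, Psi)
# on the accelerated-failure-time scale log b_j = kappa_j + lambda_j L.
# All node-level work is done on n x K matrices (K = quad^D nodes).

# Bernoulli-log disease terms and their first two derivatives in eta.
# y is a 0/1 numeric vector (recycled column-wise over node matrices).
.dis_terms <- function(eta, y, sharp, eps, need2 = FALSE) {
  sc <- .softcap(eta, sharp, eps)
  em <- pmin(expm1(sc$h), -1e-300)       # e^h - 1 in (-1, 0)
  r <- -(em + 1) / em                    # e^h / (1 - e^h)
  y0 <- 1 - y
  val <- y * sc$h + y0 * log(-em)
  a1 <- (y - y0 * r) * sc$d1
  a2 <- NULL
  if (need2)
    a2 <- y * sc$d2 - y0 * (r * (1 + r) * sc$d1^2 + r * sc$d2)
  list(val = val, a1 = a1, a2 = a2)
}

# Main evaluator.
#   theta: packed parameter vector;  model: from .prepare_model
#   quad:  nodes per latent dimension
#   score: return per-person score matrix and gradient
#   eb:    return empirical-Bayes posterior means/SDs of the latents
#   use_disease: include the disease term (FALSE for indicator-only
#     conditioning of EB scores; ignored when the spec has no disease model)
#   modes: optional n x D warm start for the posterior modes
.gsem_eval <- function(theta, model, quad = 9L, score = FALSE, eb = FALSE,
                       use_disease = TRUE, modes = NULL,
                       sharp = 0.01, eps = 1e-8, ucap = 50,
                       newton_maxit = 60L, newton_tol = 1e-11) {
  n <- model$n; D <- model$D
  w <- model$w
  has_dis <- !is.null(model$X) && use_disease
  # reject absurd parameter regions outright (BFGS line searches can probe
  # them); the optimizer treats -Inf as a rejected step
  # Admissible region: reject absurd parameters outright. The log-shape bound
  # also blocks the unbounded-likelihood degeneracy of Weibull measurement
  # models (shape -> Inf concentrates each density at its own observation);
  # shapes of weekly activity times live around 0.5-3.
  psi_diag <- if (D == 2L) model$map$psi[c(1L, 3L)] else model$map$psi
  bad_theta <- any(!is.finite(theta)) || max(abs(theta)) > 1e6 ||
    (length(unlist(model$map$logshape)) &&
       max(abs(theta[unlist(model$map$logshape)])) > 5) ||
    (length(psi_diag) && max(abs(theta[psi_diag])) > 30)
  if (bad_theta)
    return(list(loglik = -Inf, contributions = rep(-Inf, n), modes = modes,
                gradient = rep(NA_real_, model$P)))
  pp <- .unpack(theta, model)

  # ---- latent-free branch -------------------------------------------------
  if (D == 0L) {
    eta <- drop(model$X %*% pp$beta_x)
    dt <- .dis_terms(eta, model$y, sharp, eps)
    lli <- dt$val
    out <- list(loglik = sum(w * lli), contributions = lli, modes = NULL)
    if (score) {
      SC <- matrix(0, n, model$P)
      SC[, model$map$beta_x] <- model$X * dt$a1
      colnames(SC) <- model$par_names
      out$score <- SC
      out$gradient <- drop(crossprod(SC, w))
    }
    return(out)
  }

  # ---- shared precomputations --------------------------------------------
  mu <- if (is.null(model$S)) matrix(0, n, D) else model$S %*% t(pp$Gamma)
  off <- if (has_dis) drop(model$X %*% pp$beta_x) else NULL
  y <- model$y
  Psi_inv <- pp$psi$Psi_inv
  prior_const <- -(D / 2) * log(2 * pi) - pp$psi$ldetC

  # per-indicator constants: A = k*(logT - kappa), cst = log k + (k-1) logT - k kappa
  A <- cst <- kl <- vector("list", D)
  for (d in seq_len(D)) {
    kd <- pp$shape[[d]]; kapd <- pp$kappa[[d]]
    lgT <- model$ind[[d]]$logT
    p_d <- model$ind[[d]]$p
    A[[d]] <- lapply(seq_len(p_d), function(j) kd[j] * (lgT[, j] - kapd[j]))
    cst[[d]] <- lapply(seq_len(p_d), function(j)
      log(kd[j]) + (kd[j] - 1) * lgT[, j] - kd[j] * kapd[j])
    kl[[d]] <- kd * pp$lambda[[d]]
  }

  # complete-data log term g and its L-derivatives at a candidate mode;
  # L is a list of D n-vectors
  g_val <- function(L) {
    g <- rep(prior_const, n)
    for (d in seq_len(D)) {
      Ld <- L[[d]]
      for (j in seq_len(model$ind[[d]]$p)) {
        u <- exp(pmin(A[[d]][[j]] - kl[[d]][j] * Ld, ucap))
        g <- g + cst[[d]][[j]] - kl[[d]][j] * Ld - u
      }
    }
    if (has_dis) {
      eta <- off
      for (d in seq_len(D)) eta <- eta + pp$beta_L[d] * L[[d]]
      g <- g + .dis_terms(eta, y, sharp, eps)$val
    }
    if (D == 1L) {
      dl <- L[[1]] - mu[, 1]
      g - 0.5 * Psi_inv[1, 1] * dl * dl
    } else {
      d1 <- L[[1]] - mu[, 1]; d2 <- L[[2]] - mu[, 2]
      g - 0.5 * (Psi_inv[1, 1] * d1 * d1 + 2 * Psi_inv[1, 2] * d1 * d2 +
                   Psi_inv[2, 2] * d2 * d2)
    }
  }

  g_all <- function(L) {
    g <- rep(prior_const, n)
    g1 <- matrix(0, n, D)
    h11 <- h22 <- h12 <- rep(0, n)
    for (d in seq_len(D)) {
      Ld <- L[[d]]
      gd <- 0; hd <- 0
      for (j in seq_len(model$ind[[d]]$p)) {
        klj <- kl[[d]][j]
        u <- exp(pmin(A[[d]][[j]] - klj * Ld, ucap))
        g <- g + cst[[d]][[j]] - klj * Ld - u
        gd <- gd + klj * (u - 1)
        hd <- hd - klj * klj * u
      }
      g1[, d] <- gd
      if (d == 1L) h11 <- hd else h22 <- hd
    }
    if (has_dis) {
      eta <- off
      for (d in seq_len(D)) eta <- eta + pp$beta_L[d] * L[[d]]
      dt <- .dis_terms(eta, y, sharp, eps, need2 = TRUE)
      g <- g + dt$val
      for (d in seq_len(D)) g1[, d] <- g1[, d] + pp$beta_L[d] * dt$a1
      h11 <- h11 + pp$beta_L[1]^2 * dt$a2
      if (D == 2L) {
        h22 <- h22 + pp$beta_L[2]^2 * dt$a2
        h12 <- h12 + pp$beta_L[1] * pp$beta_L[2] * dt$a2
      }
    }
    if (D == 1L) {
      dl <- L[[1]] - mu[, 1]
      g <- g - 0.5 * Psi_inv[1, 1] * dl * dl
      g1[, 1] <- g1[, 1] - Psi_inv[1, 1] * dl
      h11 <- h11 - Psi_inv[1, 1]
    } else {
      dl1 <- L[[1]] - mu[, 1]; dl2 <- L[[2]] - mu[, 2]
      g <- g - 0.5 * (Psi_inv[1, 1] * dl1 * dl1 + 2 * Psi_inv[1, 2] * dl1 * dl2 +
                        Psi_inv[2, 2] * dl2 * dl2)
      g1[, 1] <- g1[, 1] - (Psi_inv[1, 1] * dl1 + Psi_inv[1, 2] * dl2)
      g1[, 2] <- g1[, 2] - (Psi_inv[1, 2] * dl1 + Psi_inv[2, 2] * dl2)
      h11 <- h11 - Psi_inv[1, 1]; h22 <- h22 - Psi_inv[2, 2]; h12 <- h12 - Psi_inv[1, 2]
    }
    list(g = g, g1 = g1, h11 = h11, h22 = h22, h12 = h12)
  }

  # ---- posterior modes by damped Newton ----------------------------------
  m <- if (!is.null(modes) && is.matrix(modes) && all(dim(modes) == c(n, D)) &&
           all(is.finite(modes))) modes else mu
  cur <- g_all(lapply(seq_len(D), function(d) m[, d]))
  for (it in seq_len(newton_maxit)) {
    if (D == 1L) {
      st1 <- -cur$g1[, 1] / pmin(cur$h11, -1e-10)
      st1[!is.finite(st1)] <- 0
      st1 <- pmin(pmax(st1, -5), 5)
      nd <- abs(cur$g1[, 1] * st1)
      nd[!is.finite(nd)] <- 0
      st <- matrix(st1, n, 1)
    } else {
      det <- cur$h11 * cur$h22 - cur$h12^2
      ok <- det > 1e-300 & cur$h11 < 0 & cur$h22 < 0
      s1 <- ifelse(ok, -(cur$h22 * cur$g1[, 1] - cur$h12 * cur$g1[, 2]) / det,
                   cur$g1[, 1] / (abs(cur$h11) + 1e-6))
      s2 <- ifelse(ok, -(cur$h11 * cur$g1[, 2] - cur$h12 * cur$g1[, 1]) / det,
                   cur$g1[, 2] / (abs(cur$h22) + 1e-6))
      s1[!is.finite(s1)] <- 0; s2[!is.finite(s2)] <- 0
      s1 <- pmin(pmax(s1, -5), 5); s2 <- pmin(pmax(s2, -5), 5)
      nd <- abs(cur$g1[, 1] * s1 + cur$g1[, 2] * s2)
      nd[!is.finite(nd)] <- 0
      st <- cbind(s1, s2)
    }
    if (max(nd) < newton_tol) break
    fac <- rep(1, n)
    mn <- m + st
    gn <- g_val(lapply(seq_len(D), function(d) mn[, d]))
    tries <- 0L
    while (tries < 12L) {
      worse <- which(gn < cur$g - 1e-10 | !is.finite(gn))
      if (!length(worse)) break
      fac[worse] <- fac[worse] / 2
      mn[worse, ] <- m[worse, , drop = FALSE] + fac[worse] * st[worse, , drop = FALSE]
      gn <- g_val(lapply(seq_len(D), function(d) mn[, d]))
      tries <- tries + 1L
    }
    still <- which(gn < cur$g - 1e-10 | !is.finite(gn))
    if (length(still)) mn[still, ] <- m[still, , drop = FALSE]  # never step downhill
    m <- mn
    cur <- g_all(lapply(seq_len(D), function(d) m[, d]))
  }

  # ---- adaptive Gauss-Hermite node matrices ------------------------------
  gh <- .gh_rule(quad)
  s2r <- sqrt(2)
  if (D == 1L) {
    K <- quad
    sig <- pmin(1 / sqrt(pmax(-cur$h11, 1e-300)), 1e6)
    Lmat <- list(m[, 1] + (s2r * sig) %o% gh$x)
    lwz <- log(gh$w) + gh$x^2
    ldetCq <- log(sig)
    lconst <- 0.5 * log(2)
  } else {
    K <- quad * quad
    a11 <- pmax(-cur$h11, 1e-300); a22 <- pmax(-cur$h22, 1e-300); a12 <- -cur$h12
    det <- pmax(a11 * a22 - a12^2, 1e-300)
    c11 <- pmin(sqrt(a22 / det), 1e6)
    c21 <- pmin(pmax(-a12 / sqrt(a22 * det), -1e6), 1e6)
    c22 <- pmin(sqrt(pmax(a11 / det - c21^2, 1e-300)), 1e6)
    k1 <- rep(seq_len(quad), times = quad)
    k2 <- rep(seq_len(quad), each = quad)
    z1 <- gh$x[k1]; z2 <- gh$x[k2]
    Lmat <- list(m[, 1] + (s2r * c11) %o% z1,
                 m[, 2] + (s2r * c21) %o% z1 + (s2r * c22) %o% z2)
    lwz <- log(gh$w[k1]) + log(gh$w[k2]) + z1^2 + z2^2
    ldetCq <- log(c11) + log(c22)
    lconst <- log(2)
  }

  # ---- g over all nodes (matrix form), with reusable pieces --------------
  U <- lapply(seq_len(D), function(d) vector("list", model$ind[[d]]$p))
  amat <- matrix(prior_const, n, K)
  for (d in seq_len(D)) {
    Ld <- Lmat[[d]]
    for (j in seq_len(model$ind[[d]]$p)) {
      u <- exp(pmin(A[[d]][[j]] - kl[[d]][j] * Ld, ucap))
      if (score) U[[d]][[j]] <- u
      amat <- amat + (cst[[d]][[j]] - kl[[d]][j] * Ld - u)
    }
  }
  a1mat <- NULL
  if (has_dis) {
    eta <- off + pp$beta_L[1] * Lmat[[1]]
    if (D == 2L) eta <- eta + pp$beta_L[2] * Lmat[[2]]
    dt <- .dis_terms(eta, y, sharp, eps)
    amat <- amat + dt$val
    if (score) a1mat <- dt$a1
  }
  dl1 <- Lmat[[1]] - mu[, 1]
  if (D == 1L) {
    amat <- amat - 0.5 * Psi_inv[1, 1] * dl1 * dl1
  } else {
    dl2 <- Lmat[[2]] - mu[, 2]
    amat <- amat - 0.5 * (Psi_inv[1, 1] * dl1 * dl1 + 2 * Psi_inv[1, 2] * dl1 * dl2 +
                            Psi_inv[2, 2] * dl2 * dl2)
  }
  amat <- amat + matrix(lwz, n, K, byrow = TRUE)
  lse <- .logsumexp_rows(amat)
  lli <- lse + lconst + ldetCq

  out <- list(loglik = sum(w * lli), contributions = lli, modes = m)
  if (!is.finite(out$loglik)) {
    out$gradient <- rep(NA_real_, model$P)
    return(out)
  }
  if (!score && !eb) return(out)

  PW <- exp(amat - lse)   # posterior node weights, rows sum to 1
  onesK <- rep(1, K)
  rsum <- function(M) drop(M %*% onesK)   # BLAS row sums

  if (eb) {
    ebm <- matrix(0, n, D); ebs <- matrix(0, n, D)
    for (d in seq_len(D)) {
      ebm[, d] <- rsum(PW * Lmat[[d]])
      ebs[, d] <- sqrt(pmax(rsum(PW * Lmat[[d]]^2) - ebm[, d]^2, 0))
    }
    colnames(ebm) <- colnames(ebs) <- model$lat_names
    out$eb <- list(mean = ebm, sd = ebs)
  }

  if (score) {
    map <- model$map
    SC <- matrix(0, n, model$P)
    for (d in seq_len(D)) {
      Ld <- Lmat[[d]]
      PL <- PW * Ld
      rPL <- rsum(PL)
      kd <- pp$shape[[d]]
      free <- map$lambda_pos[[d]]
      fi <- 0L
      for (j in seq_len(model$ind[[d]]$p)) {
        u <- U[[d]][[j]]
        PU <- PW * u
        rPU <- rsum(PU)
        SC[, map$kappa[[d]][j]] <- kd[j] * (rPU - 1)
        if (j %in% free) {
          fi <- fi + 1L
          SC[, map$lambda[[d]][fi]] <- kd[j] * (rsum(PU * Ld) - rPL)
        }
        # d logW / d log k = 1 + k * (logT - kappa - lambda L) * (1 - u)
        aj <- A[[d]][[j]] / kd[j]
        SC[, map$logshape[[d]][j]] <- 1 + kd[j] *
          (aj * (1 - rPU) - pp$lambda[[d]][j] * (rPL - rsum(PU * Ld)))
      }
    }
    if (has_dis) {
      Pa1 <- rsum(PW * a1mat)
      SC[, map$beta_x] <- model$X * Pa1
      for (d in seq_len(D))
        SC[, map$beta_L[d]] <- rsum(PW * a1mat * Lmat[[d]])
    }
    # prior block: structural paths and covariance (log-Cholesky)
    if (D == 1L) {
      Pd1 <- rsum(PW * dl1)
      Pd1s <- rsum(PW * dl1 * dl1)
      if (!is.null(map$gamma))
        SC[, map$gamma[1, ]] <- model$S * (Psi_inv[1, 1] * Pd1)
      SC[, map$psi] <- -1 + Psi_inv[1, 1] * Pd1s
    } else {
      Pd1 <- rsum(PW * dl1); Pd2 <- rsum(PW * dl2)
      if (!is.null(map$gamma)) {
        pid1 <- Psi_inv[1, 1] * Pd1 + Psi_inv[1, 2] * Pd2
        pid2 <- Psi_inv[1, 2] * Pd1 + Psi_inv[2, 2] * Pd2
        SC[, map$gamma[1, ]] <- model$S * pid1
        SC[, map$gamma[2, ]] <- model$S * pid2
      }
      chp <- pp$psi$chol_pars
      c1 <- exp(chp[1]); c21p <- chp[2]; c3 <- exp(chp[3])
      V1 <- dl1 / c1
      V2 <- (dl2 - c21p * V1) / c3
      SC[, map$psi[1]] <- -1 + rsum(PW * (V1 * (V1 - V2 * (c21p / c3))))
      SC[, map$psi[2]] <- rsum(PW * V1 * V2) / c3
      SC[, map$psi[3]] <- -1 + rsum(PW * V2 * V2)
    }
    colnames(SC) <- model$par_names
    out$score <- SC
    out$gradient <- drop(crossprod(SC, w))
  }
  out
}

#' Joint GSEM log-likelihood at a given parameter vector
#'
#' Evaluates the integrated log-likelihood (adaptive Gauss-Hermite quadrature
#' over the latent dimensions, centred at the per-person posterior mode with
#' curvature rescaling) together with per-person contributions. Expansion
#' factors declared in the spec multiply the log contributions in the total.
#'
#' @param spec a [gsem_spec()].
#' @param data person-level data frame.
#' @param theta packed parameter vector in the documented packing order (see
#'   [gsem_start()] for names); defaults to the start values.
#' @param quad quadrature nodes per latent dimension (at least 3); `NULL`
#'   uses the same default as [fit_gsem()].
#' @return List with `loglik` (weighted total) and `contributions`
#'   (per-person, unweighted).
#' @export
gsem_loglik <- function(spec, data, theta = NULL, quad = NULL) {
  model <- .prepare_model(spec, data)
  if (is.null(quad)) quad <- if (model$D >= 2L) 13L else 41L
  if (quad < 3) .stopf("quadrature needs at least 3 nodes per dimension")
  if (is.null(theta)) theta <- .gsem_start(model)
  if (length(theta) != model$P)
    .stopf("theta has length %d, expected %d", length(theta), model$P)
  ev <- .gsem_eval(theta, model, quad = as.integer(quad))
  if (!is.finite(ev$loglik))
    .stopf("non-finite likelihood contribution at record %s",
           paste(utils::head(which(!is.finite(ev$contributions)), 3), collapse = ", "))
  list(loglik = ev$loglik, contributions = ev$contributions)
}
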