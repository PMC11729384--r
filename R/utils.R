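# Internal numerical helpers shared across the likelihood and diagnostics code.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Row-wise log-sum-exp of an n x K matrix, guarded against all -Inf rows.
.logsumexp_rows <- function(a) {
  K <- ncol(a)
  m <- a[, 1L]
  if (K > 1L) for (k in 2L:K) m <- pmax(m, a[, k])
  m[!is.finite(m)] <- 0  # rows that are all -Inf stay -Inf via log(0)
  m + log(rowSums(exp(a - m)))
}

# Gauss-Hermite rule (physicists' weight exp(-x^2)) via Golub-Welsch.
# Returns nodes in increasing order and weights summing to sqrt(pi).
.gh_rule <- function(q) {
  q <- as.integer(q)
  if (q < 1L) .stopf("quadrature rule needs at least 1 node")
  if (q == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(q - 1L)
  J <- matrix(0, q, q)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Smooth cap of the log-link linear predictor just below 0 so that the
# Bernoulli likelihood pi = exp(eta) stays a proper probability during
# optimization. h(eta) = eta - s*softplus((eta + eps)/s) tends to eta for
# eta << 0 and to -eps for eta >> 0; h is increasing and concave.
# Returns the capped value and its first two derivatives in eta.
.softcap <- function(eta, sharp = 0.01, eps = 1e-8) {
  x <- (eta + eps) / sharp
  bad <- which(!is.finite(x))
  if (length(bad)) x[bad] <- 0          # patched below
  ax <- abs(x)
  emx <- exp(-ax)                       # exp(-|x|), never overflows
  sp <- pmax(x, 0) + log1p(emx)         # stable softplus
  d1 <- emx / (1 + emx)                 # plogis(-x) for x >= 0 ...
  neg <- which(x < 0)
  d1[neg] <- 1 / (1 + emx[neg])         # ... and for x < 0
  h <- eta - sharp * sp
  d2 <- -d1 * (1 - d1) / sharp
  if (length(bad)) {                    # infinite or NaN linear predictors
    pinf <- bad[!is.na(eta[bad]) & eta[bad] > 0]
    ninf <- bad[!is.na(eta[bad]) & eta[bad] < 0]
    nan <- bad[is.na(eta[bad])]
    h[pinf] <- -eps; d1[pinf] <- 0; d2[pinf] <- 0
    h[ninf] <- eta[ninf]; d1[ninf] <- 1; d2[ninf] <- 0
    h[nan] <- NaN; d1[nan] <- 0; d2[nan] <- 0
  }
  list(h = h, d1 = d1, d2 = d2)
}

# log(1 - exp(h)) for h < 0; absolute error is negligible for very negative h.
.log1mexp <- function(h) log(-expm1(h))

.check_prob_vector <- function(p, field) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    .stopf("configuration error in '%s': probabilities must be nonnegative and sum to 1", field)
  invisible(p)
}

.check_pos <- function(x, field) {
  if (any(!is.finite(x)) || any(x <= 0))
    .stopf("configuration error in '%s': values must be finite and positive", field)
  invisible(x)
}

# Central-difference Hessian of a scalar function from its analytic gradient.
.num_hessian <- function(grad_fun, theta, step = NULL) {
  P <- length(theta)
  if (is.null(step)) step <- 1e-5 * pmax(1, abs(theta))
  H <- matrix(0, P, P)
  for (i in seq_len(P)) {
    tp <- theta; tp[i] <- tp[i] + step[i]
    tm <- theta; tm[i] <- tm[i] - step[i]
    H[i, ] <- (grad_fun(tp) - grad_fun(tm)) / (2 * step[i])
  }
  (H + t(H)) / 2
}
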