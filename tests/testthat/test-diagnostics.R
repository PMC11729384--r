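# Measurement diagnostics: distribution selection, KMO, Bartlett sphericity,
# principal-axis loadings.

test_that("distribution ranking recovers known generating families", {
  withr::with_seed(21, {
    xe <- rexp(5000, rate = 1 / 420)
    ge <- distribution_gof(xe)
    wb <- ge[ge$family == "weibull", ]
    expect_lt(abs(wb$pars[[1]][["shape"]] - 1), 0.05)   # exponential is shape-1 Weibull

    xw <- rweibull(5000, shape = 2, scale = 100)
    gw <- distribution_gof(xw)
    expect_lt(abs(gw$pars[gw$family == "weibull"][[1]][["shape"]] - 2), 0.1)
  })
  # Weibull beats lognormal by AIC in nearly all replicates
  withr::with_seed(22, {
    wins <- 0L
    for (r in 1:20) {
      x <- rweibull(5000, 2, 100)
      g <- distribution_gof(x, families = c("weibull", "lognormal"))
      if (g$family[1] == "weibull") wins <- wins + 1L
    }
    expect_gte(wins, 18L)
  })
  expect_error(distribution_gof(c(-1, 1:20)), "positive")
  expect_error(distribution_gof(1:5), "at least 10")
})

test_that("AIC ranking is invariant to data order", {
  withr::with_seed(23, x <- rweibull(2000, 1.5, 50))
  g1 <- distribution_gof(x)
  g2 <- distribution_gof(rev(x))
  expect_equal(g1$family, g2$family)
  expect_equal(g1$aic, g2$aic, tolerance = 1e-8)
})

test_that("KMO equals 0.5 for any bivariate correlation and matches a partial-correlation oracle", {
  for (r in c(-0.7, 0.2, 0.6)) {
    R <- matrix(c(1, r, r, 1), 2, 2)
    expect_equal(kmo_statistic(R)$overall, 0.5, tolerance = 1e-12)
  }
  # 3x3 oracle via the recursive partial-correlation formula
  R3 <- diag(3); R3[1, 2] <- R3[2, 1] <- 0.6
  km <- kmo_statistic(R3)
  pc <- function(rij, rik, rjk) (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  q12 <- pc(0.6, 0, 0); q13 <- pc(0, 0.6, 0); q23 <- pc(0, 0, 0.6)
  r2 <- 2 * 0.6^2
  q2 <- 2 * (q12^2 + q13^2 + q23^2)
  expect_equal(km$overall, r2 / (r2 + q2 / 1), tolerance = 1e-10)

  expect_error(kmo_statistic(diag(3)), "identity")
  R_sing <- matrix(1, 3, 3)
  expect_error(kmo_statistic(R_sing), "singular")
})

test_that("KMO is invariant to variable reordering and stays in (0, 1]", {
  withr::with_seed(8, {
    M <- matrix(rnorm(600), 100, 6) %*% matrix(rnorm(36, sd = 0.6), 6, 6)
    R <- cor(M)
    k0 <- kmo_statistic(R)$overall
    expect_gt(k0, 0); expect_lte(k0, 1)
    pm <- sample(6)
    expect_equal(kmo_statistic(R[pm, pm])$overall, k0, tolerance = 1e-10)
  })
})

test_that("Bartlett sphericity matches its closed form", {
  expect_equal(bartlett_sphericity(diag(4), 50)$statistic, 0, tolerance = 1e-12)
  expect_equal(bartlett_sphericity(diag(4), 50)$p_value, 1)
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  b <- bartlett_sphericity(R, 100)
  expect_equal(b$statistic, -97.5 * log(0.75), tolerance = 1e-10)
  expect_lt(abs(b$statistic - 28.05), 0.01)
  expect_equal(b$df, 1L)
  expect_lt(b$p_value, 1e-6)
  # monotone in |r| for fixed p, n
  stats <- sapply(c(0.1, 0.3, 0.5, 0.7), function(r)
    bartlett_sphericity(matrix(c(1, r, r, 1), 2), 100)$statistic)
  expect_true(all(diff(stats) > 0))
  expect_error(bartlett_sphericity(matrix(c(1, 2, 2, 1), 2), 100), "positive definite")
})

test_that("principal-axis factoring recovers a planted two-block structure", {
  R <- matrix(0, 6, 6)
  R[1:3, 1:3] <- 0.5; R[4:6, 4:6] <- 0.5; diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  fl <- extract_factor_loadings(R, 2)
  dom <- apply(abs(fl$loadings), 1, which.max)
  expect_equal(length(unique(dom[1:3])), 1L)
  expect_equal(length(unique(dom[4:6])), 1L)
  expect_false(dom[1] == dom[4])

  fl0 <- extract_factor_loadings(diag(5), 2)
  expect_lt(max(fl0$communalities), 0.05)
  expect_error(extract_factor_loadings(diag(4), 4), "n_factors")
})

test_that("indicator correlations are computed on the log scale", {
  d <- generate_dataset(synthetic_config(n_persons = 800), seed = 5)
  R <- indicator_correlations(d)
  expect_equal(dim(R), c(6, 6))
  expect_equal(diag(R), rep(1, 6), ignore_attr = TRUE)
  expect_equal(attr(R, "n"), 800)
  expect_gt(abs(R["computer_smartphone", "tv"]), 0.05)  # shared latent induces correlation
})
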