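# The joint likelihood: packing, factorization, quadrature accuracy against
# independent integration oracles, analytic scores, and symmetry.

test_that("parameter packing round-trips and carries documented names", {
  d <- generate_dataset(mild_config(300), seed = 1)
  spec <- full_spec()
  model <- gsempa:::.prepare_model(spec, d)
  th <- gsem_start(spec, d)
  expect_equal(length(th), model$P)
  pp <- gsempa:::.unpack(th, model)
  expect_equal(pp$kappa[[1]], unname(th[1:3]), ignore_attr = TRUE)
  expect_equal(pp$lambda[[1]][1], 1)                       # reference fixed
  expect_equal(pp$lambda[[1]][2:3], unname(th[4:5]))
  expect_equal(pp$shape[[2]], exp(unname(th[14:16])), ignore_attr = TRUE)
  expect_true(all(c("psi.logchol.screens", "disease.L.transport",
                    "gamma.transport.leisure_pa") %in% names(th)))
  # Psi is SPD by construction
  expect_true(all(eigen(pp$psi$Psi)$values > 0))
})

test_that("likelihood factorizes when the latents decouple", {
  cfg <- mild_config(120)
  d <- generate_dataset(cfg, seed = 2)
  spec <- full_spec()
  model <- gsempa:::.prepare_model(spec, d)
  th <- gsem_start(spec, d)
  nm <- names(th)
  # free loadings 0, near-degenerate latents, no paths, no latent disease terms
  th[grepl("\\.lambda\\.", nm)] <- 0
  th[grepl("^gamma\\.", nm)] <- 0
  th[grepl("^psi\\.logchol", nm)] <- log(1e-6)
  th[nm == "psi.chol.transport.screens"] <- 0
  th[grepl("^disease\\.L\\.", nm)] <- 0
  ll <- gsem_loglik(spec, d, theta = th)

  kap <- th[grepl("\\.kappa\\.", nm)]
  shp <- exp(th[grepl("\\.logshape\\.", nm)])
  inds <- c("computer_smartphone", "tv", "video_games",
            "motor_vehicle", "cycling", "walking")
  manual <- rep(0, nrow(d))
  for (j in seq_along(inds))
    manual <- manual + dweibull(d[[inds[j]]], shape = shp[j],
                                scale = exp(kap[j]), log = TRUE)
  X <- model.matrix(~ sex + age + ethnicity + schooling + wealth_quartile +
                      energy_kcal + leisure_pa, d)
  eta <- drop(X %*% th[grepl("^disease\\.", nm) & !grepl("disease\\.L\\.", nm)])
  manual <- manual + dbinom(d$obesity, 1, pmin(exp(eta), 1), log = TRUE)
  expect_equal(ll$contributions, manual, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("quadrature agrees with a Monte-Carlo integration oracle", {
  cfg <- synthetic_config(n_persons = 50)
  d <- generate_dataset(cfg, seed = 3)
  spec <- full_spec()
  th <- true_theta(spec, d)
  ll <- gsem_loglik(spec, d, theta = th)

  # oracle: 100,000 prior draws per person, plain average of the integrand
  sds <- cfg$latent_sds; rho <- cfg$latent_corr
  Sig <- diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds)
  Ch <- chol(Sig)
  R <- 100000
  withr::with_seed(99, Z <- matrix(rnorm(2 * R), R, 2) %*% Ch)
  X <- model.matrix(~ sex + age + ethnicity + schooling + wealth_quartile +
                      energy_kcal + leisure_pa, d)
  bx <- th[grepl("^disease\\.", names(th)) & !grepl("disease\\.L\\.", names(th))]
  off <- drop(X %*% bx)
  bl <- th[grepl("^disease\\.L\\.", names(th))]
  mc <- numeric(50)
  for (i in 1:50) {
    L1 <- cfg$gamma[["screens"]] * d$leisure_pa[i] + Z[, 1]
    L2 <- cfg$gamma[["transport"]] * d$leisure_pa[i] + Z[, 2]
    lg <- 0
    for (lat in c("screens", "transport")) {
      L <- if (lat == "screens") L1 else L2
      for (j in names(cfg$loadings[[lat]]))
        lg <- lg + dweibull(d[[j]][i], shape = cfg$shapes[[lat]][[j]],
                            scale = exp(cfg$intercepts[[lat]][[j]] +
                                          cfg$loadings[[lat]][[j]] * L), log = TRUE)
    }
    eta <- off[i] + bl[1] * L1 + bl[2] * L2
    lg <- lg + dbinom(d$obesity[i], 1, pmin(exp(eta), 1), log = TRUE)
    m <- max(lg)
    mc[i] <- m + log(mean(exp(lg - m)))
  }
  expect_lt(abs(sum(mc) - ll$loglik) / abs(ll$loglik), 0.001)
})

test_that("the quadrature rule is effectively converged in the node count", {
  d <- generate_dataset(synthetic_config(n_persons = 300), seed = 4)
  spec <- full_spec()
  th <- gsem_start(spec, d)
  l7 <- gsem_loglik(spec, d, theta = th, quad = 7)$loglik
  l15 <- gsem_loglik(spec, d, theta = th, quad = 15)$loglik
  expect_lt(abs(l7 - l15) / abs(l15), 1e-4)
  l13 <- gsem_loglik(spec, d, theta = th, quad = 13)$loglik
  l21 <- gsem_loglik(spec, d, theta = th, quad = 21)$loglik
  expect_lt(abs(l13 - l21) / abs(l21), 1e-5)
})

test_that("analytic scores match central finite differences", {
  d <- generate_dataset(mild_config(150), seed = 6)
  spec <- full_spec()
  model <- gsempa:::.prepare_model(spec, d)
  th <- gsem_start(spec, d)
  ev <- gsempa:::.gsem_eval(th, model, quad = 13L, score = TRUE)
  expect_equal(dim(ev$score), c(150L, model$P))
  expect_equal(colSums(ev$score), ev$gradient, ignore_attr = TRUE, tolerance = 1e-10)
  for (i in seq_len(model$P)) {
    h <- 1e-6 * max(1, abs(th[i]))
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    fd <- (gsempa:::.gsem_eval(tp, model, quad = 13L)$loglik -
             gsempa:::.gsem_eval(tm, model, quad = 13L)$loglik) / (2 * h)
    expect_lt(abs(fd - ev$gradient[i]) / max(abs(fd), 1), 5e-3)
  }
})

test_that("relabelling the latents leaves the likelihood unchanged", {
  cfg <- mild_config(100)
  d <- generate_dataset(cfg, seed = 7)
  spec1 <- full_spec()
  spec2 <- gsem_spec(
    latents = list(transport = c("motor_vehicle", "cycling", "walking"),
                   screens = c("computer_smartphone", "tv", "video_games")),
    disease = obesity ~ sex + age + ethnicity + schooling + wealth_quartile +
      energy_kcal + leisure_pa,
    structural = ~ leisure_pa)
  th1 <- true_theta(spec1, d)
  th2 <- true_theta(spec2, d)  # helper rebuilds psi for the swapped order
  # swapped-order covariance block must describe the same Psi
  sds <- cfg$latent_sds; rho <- cfg$latent_corr
  th2[names(th2) == "psi.logchol.transport"] <- log(sds[["transport"]])
  th2[names(th2) == "psi.chol.screens.transport"] <- sds[["screens"]] * rho
  th2[names(th2) == "psi.logchol.screens"] <- log(sds[["screens"]] * sqrt(1 - rho^2))
  l1 <- gsem_loglik(spec1, d, theta = th1, quad = 15)$loglik
  l2 <- gsem_loglik(spec2, d, theta = th2, quad = 15)$loglik
  expect_equal(l1, l2, tolerance = 1e-8)
})

test_that("weights multiply log contributions", {
  d <- generate_dataset(mild_config(80), seed = 8)
  d$expansion_factor <- 2
  spec_w <- gsem_spec(latents = list(screens = c("computer_smartphone", "tv", "video_games")),
                      weights = "expansion_factor")
  spec_u <- screens_spec()
  th <- gsem_start(spec_u, d)
  lu <- gsem_loglik(spec_u, d, theta = th)
  lw <- gsem_loglik(spec_w, d, theta = th)
  expect_equal(lw$loglik, 2 * lu$loglik, tolerance = 1e-9)
  expect_equal(lw$contributions, lu$contributions, tolerance = 1e-12)
})
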