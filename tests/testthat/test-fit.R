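# Fitting: GLM oracle equivalence, recovery, weighting contract,
# convergence flags and covariance structure.

glm_fit_cached <- local({
  env <- new.env()
  function() {
    if (is.null(env$res)) {
      d <- generate_dataset(latent_free_config(4000), seed = 10)
      spec <- latent_free_spec()
      fit <- fit_gsem(spec, d)
      X <- model.matrix(~ sex + age + ethnicity + wealth_quartile + leisure_pa, d)
      st <- c(log(mean(d$obesity)), rep(0, ncol(X) - 1))
      glm0 <- glm(obesity ~ sex + age + ethnicity + wealth_quartile + leisure_pa,
                  family = binomial(link = "log"), data = d, start = st,
                  control = glm.control(epsilon = 1e-12, maxit = 200))
      env$res <- list(d = d, fit = fit, glm = glm0)
    }
    env$res
  }
})

test_that("a latent-free fit matches an independent log-link Bernoulli GLM to 6 significant figures", {
  res <- glm_fit_cached()
  expect_true(res$fit$converged)
  b1 <- coef(res$fit)
  b2 <- coef(res$glm)
  expect_equal(length(b1), length(b2))
  # agreement limited by the GLM's own deviance-based stopping rule ...
  expect_lt(max(abs(b1 - b2) / pmax(abs(b2), 1e-8)), 5e-6)
  expect_gte(logLik(res$fit)[1], as.numeric(logLik(res$glm)) - 1e-7)
  # ... so also verify our estimate is an IRLS fixed point at 6 digits:
  # one IRLS pass started at our optimum must not move any coefficient
  refine <- glm(obesity ~ sex + age + ethnicity + wealth_quartile + leisure_pa,
                family = binomial(link = "log"), data = res$d,
                start = unname(b1),
                control = glm.control(epsilon = 1e-14, maxit = 100))
  b3 <- coef(refine)
  big <- abs(b3) > 0.01   # 6 significant figures where they are meaningful,
  expect_lt(max(abs(b1 - b3)[big] / abs(b3)[big]), 1e-6)
  if (any(!big)) expect_lt(max(abs(b1 - b3)[!big]), 1e-8)
})

test_that("robust and model-based standard errors agree under correct specification", {
  res <- glm_fit_cached()
  se_m <- sqrt(diag(vcov(res$fit, type = "model")))
  se_r <- sqrt(diag(vcov(res$fit, type = "robust")))
  expect_equal(dim(vcov(res$fit)), c(length(coef(res$fit)), length(coef(res$fit))))
  expect_lt(max(abs(vcov(res$fit) - t(vcov(res$fit)))), 1e-8)
  expect_true(all(diag(vcov(res$fit)) >= 0))
  expect_lt(max(abs(se_r / se_m - 1)), 0.15)
})

test_that("information criteria follow their definitions", {
  res <- glm_fit_cached()
  ic <- information_criteria(res$fit)
  k <- length(coef(res$fit))
  expect_equal(unname(ic["AIC"]), 2 * k - 2 * res$fit$loglik)
  expect_equal(unname(ic["BIC"]), k * log(4000) - 2 * res$fit$loglik)
  expect_equal(unname(ic["AIC"]), AIC(res$fit))
  expect_equal(unname(ic["BIC"]), BIC(res$fit))
})

test_that("measurement-model fit recovers moderate loadings", {
  cfg <- mild_config(4000, gamma = c(screens = 0, transport = 0))
  d <- generate_dataset(cfg, seed = 11)
  fit <- fit_gsem(screens_spec(), d, se = FALSE)
  expect_true(fit$converged)
  co <- coef(fit)
  expect_lt(abs(co[["screens.lambda.tv"]] - 2), 0.4)
  expect_lt(abs(co[["screens.lambda.video_games"]] + 3), 0.5)
  expect_lt(abs(exp(co[["psi.logsd.screens"]]) - 0.3), 0.06)
  expect_lt(abs(co[["screens.kappa.tv"]] - log(420)), 0.1)
  expect_lt(abs(exp(co[["screens.logshape.tv"]]) - 1.3), 0.1)
})

test_that("duplicating records at half weight reproduces the unweighted fit", {
  cfg <- mild_config(500, gamma = c(screens = 0, transport = 0))
  d <- generate_dataset(cfg, seed = 12)
  d$expansion_factor <- 1
  dd <- rbind(d, d)
  dd$expansion_factor <- 0.5
  spec_u <- screens_spec()
  spec_w <- gsem_spec(latents = list(screens = c("computer_smartphone", "tv", "video_games")),
                      weights = "expansion_factor")
  f1 <- fit_gsem(spec_u, d, se = FALSE)
  f2 <- fit_gsem(spec_w, dd, se = FALSE)
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
})

test_that("non-convergence is flagged, never silently accepted", {
  d <- generate_dataset(mild_config(400), seed = 13)
  fit <- fit_gsem(screens_spec(), d, se = FALSE,
                  control = gsem_control(maxit = 1, prefit = FALSE, polish = FALSE))
  expect_false(fit$converged)
  expect_error(robust_vcov(fit), "precondition")
  expect_error(eb_scores(fit), "precondition")
})

test_that("precondition and input errors carry useful messages", {
  d <- generate_dataset(mild_config(120), seed = 14)
  expect_error(fit_gsem(full_spec(), d[1:20, ]), "free parameters")
  d_bad <- d; d_bad$tv[3] <- 0
  expect_error(fit_gsem(screens_spec(), d_bad), "positive")
  expect_error(gsem_spec(latents = list(a = "tv", b = "tv")), "exactly one latent")
})

test_that("the fitted-model methods behave like standard modelling objects", {
  res <- glm_fit_cached()
  fit <- res$fit
  expect_output(print(fit), "log-link")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gsem_fit")
  expect_output(print(sm), "Estimate")
  ci <- confint(fit)
  expect_equal(rownames(ci), names(coef(fit)))
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(nobs(fit), 4000)
  expect_equal(attr(logLik(fit), "df"), length(coef(fit)))
  pr <- predict(fit, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  rs <- residuals(fit)
  expect_equal(length(rs), 4000)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(length(sims), 2L)
  expect_true(all(sims[[1]]$obesity %in% 0:1))
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf)); unlink(pf)

  # latent model methods: scores via predict, simulate regenerates indicators
  tr <- transport_fit_for_methods()
  sc <- predict(tr$fit, type = "scores")
  expect_true(all(c("transport_mean", "transport_sd", "transport_tertile") %in% names(sc)))
  s2 <- simulate(tr$fit, nsim = 1, seed = 2)[[1]]
  expect_true(all(c("motor_vehicle", "cycling", "walking") %in% names(s2)))
  expect_true(all(s2$motor_vehicle > 0))
})
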