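# The synthetic survey generator: marginal structure, determinism,
# calibration and exclusion rules.

test_that("generation is deterministic and respects basic record invariants", {
  cfg <- synthetic_config(n_persons = 400)
  d1 <- generate_dataset(cfg, seed = 7)
  d2 <- generate_dataset(cfg, seed = 7)
  expect_identical(d1, d2)
  d3 <- generate_dataset(cfg, seed = 8)
  expect_false(identical(d1$tv, d3$tv))
  expect_true(all((d1$obesity == 1) == (d1$bmi >= 30)))
  times <- c("computer_smartphone", "tv", "video_games",
             "motor_vehicle", "cycling", "walking")
  expect_true(all(as.matrix(d1[times]) > 0))
  expect_true(all(d1$expansion_factor > 0))
  expect_true(all(d1$age >= 18 & d1$age <= 64))
})

test_that("an empty request yields an empty dataset without error", {
  d <- generate_dataset(synthetic_config(n_persons = 0), seed = 1)
  expect_equal(nrow(d), 0L)
  expect_true(all(c("sex", "tv", "obesity", "department") %in% names(d)))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(synthetic_config(latent_corr = 1), "latent_corr")
  expect_error(synthetic_config(n_persons = -3), "n_persons")
  expect_error(synthetic_config(ethnicity_probs = c(other = 0.5, afro = 0.2, indigenous = 0.2)),
               "ethnicity_probs")
  expect_error(synthetic_config(shapes = list(
    screens = c(computer_smartphone = 1.3, tv = -1, video_games = 1.3),
    transport = c(motor_vehicle = 1.3, cycling = 1.3, walking = 1.3))), "shapes")
})

test_that("Weibull indicator sampler matches closed-form moments", {
  withr::with_seed(42, {
    x <- sample_weibull_indicator(rep(0, 1e5), 0, log(420), 1)
    expect_lt(abs(mean(x) - 420), 5)          # shape 1 is exponential
    y <- sample_weibull_indicator(rep(0, 1e5), 0, log(100), 2)
    expect_lt(abs(median(y) - 100 * sqrt(log(2))), 1)
    L <- rnorm(1e4)
    z <- sample_weibull_indicator(L, 0, log(50), 1.5)
    expect_lt(abs(cor(log(z), L)), 0.03)      # zero loading decouples
  })
  expect_error(sample_weibull_indicator(1:3, 1, 0, 0), "shape")
})

test_that("log-link obesity sampler honours the capped-probability contract", {
  expect_equal(as.vector(sample_obesity(rep(-Inf, 5))), rep(0L, 5))
  f1 <- sample_obesity(rep(0, 10))          # pi = 1 exactly, not capped
  expect_equal(as.vector(f1), rep(1L, 10))
  expect_warning(f2 <- sample_obesity(rep(0.5, 10)), "capped")
  expect_equal(as.vector(f2), rep(1L, 10))
  expect_equal(attr(f2, "capped_fraction"), 1)
  withr::with_seed(9, {
    f <- sample_obesity(rep(log(0.2), 1e5))
    expect_lt(abs(mean(f) - 0.2), 0.005)
  })
  expect_equal(attr(sample_obesity(rep(log(0.5), 10)), "capped_fraction"), 0)
})

test_that("default configuration reproduces the study's marginal structure", {
  d <- generate_dataset(synthetic_config(n_persons = 9658), seed = 20)
  expect_lt(abs(mean(d$obesity) - 0.191), 0.013)
  expect_lt(attr(d, "capped_fraction"), 0.001)
  expect_lt(abs(mean(d$sex == "female") - 0.562), 0.02)
  expect_lt(abs(mean(d$ethnicity == "afro") - 0.071), 0.01)
  expect_lt(abs(mean(d$age) - 38.5), 1.5)
})

test_that("latent draws match the configured scale, correlation and margins", {
  cfg <- synthetic_config(n_persons = 50000, gamma = c(screens = 0, transport = 0))
  d <- generate_dataset(cfg, seed = 13)
  expect_lt(abs(sd(d$true_screens) / 0.1 - 1), 0.03)
  expect_lt(abs(sd(d$true_transport) / 0.5 - 1), 0.03)
  expect_lt(abs(cor(d$true_screens, d$true_transport) - 0.2), 0.02)
  # marginal Weibull when nothing loads on the latents
  cfg0 <- synthetic_config(
    n_persons = 50000, gamma = c(screens = 0, transport = 0),
    loadings = list(screens = c(computer_smartphone = 0, tv = 0, video_games = 0),
                    transport = c(motor_vehicle = 0, cycling = 0, walking = 0)))
  d0 <- generate_dataset(cfg0, seed = 14)
  for (v in c("tv", "cycling")) {
    lat <- if (v == "tv") "screens" else "transport"
    xs <- sort(d0[[v]])
    cdf <- pweibull(xs, shape = cfg0$shapes[[lat]][[v]],
                    scale = exp(cfg0$intercepts[[lat]][[v]]))
    n <- length(xs)
    ks <- max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
    expect_lt(ks, 0.01)
  }
  # and the log-times decorrelate
  R <- cor(log(as.matrix(d0[1:10000, c("computer_smartphone", "tv", "video_games",
                                       "motor_vehicle", "cycling", "walking")])))
  expect_lt(max(abs(R[upper.tri(R)])), 0.03)
})

test_that("eligibility exclusions match a direct sort-and-slice oracle", {
  df <- data.frame(age = c(rep(30, 8), 70, 70), energy_kcal = seq(1500, 2400, 100))
  out <- apply_exclusions(df)
  expect_equal(nrow(out$records), 8L)
  expect_equal(out$log$removed[out$log$criterion == "age"], 2L)

  withr::with_seed(5, {
    df2 <- data.frame(age = sample(18:64, 1000, TRUE), energy_kcal = rlnorm(1000, 7.6, 0.3))
  })
  out2 <- apply_exclusions(df2)
  # oracle: nearest-rank percentile bounds from the sorted energies
  xs <- sort(df2$energy_kcal); n <- length(xs)
  qt <- function(p) xs[max(1L, ceiling(n * p))]
  kept_oracle <- sum(df2$energy_kcal >= qt(0.01) & df2$energy_kcal <= qt(0.99))
  expect_equal(nrow(out2$records), kept_oracle)
  expect_gte(nrow(out2$records), 980L)

  # identity when nothing is excludable
  df3 <- data.frame(age = rep(40, 5), energy_kcal = rep(2000, 5))
  expect_identical(apply_exclusions(df3)$records, df3)
  empty <- apply_exclusions(df3[0, ])
  expect_equal(nrow(empty$records), 0L)
  expect_equal(nrow(empty$log), 0L)
})

test_that("datasets are written with a config sidecar", {
  d <- generate_dataset(synthetic_config(n_persons = 20), seed = 3)
  tmp <- tempfile(fileext = ".csv")
  paths <- write_dataset(d, tmp)
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths[2])
  expect_equal(side$seed, 3)
  expect_equal(side$n_persons, 20)
  unlink(paths)
})
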