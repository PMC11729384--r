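# Descriptive comparisons: obesity classification, weighted prevalence,
# chi-square and Mann-Whitney wrappers.

test_that("obesity classification is boundary-inclusive at BMI 30", {
  expect_equal(classify_obesity(c(30, 29.99, 31.14)), c(1L, 0L, 1L))
  expect_equal(classify_obesity(90 / 1.70^2), 1L)    # 31.14 from weight/height
  expect_error(classify_obesity(c(25, -1)), "domain error")
  expect_error(classify_obesity(c(25, NA)), "domain error")
})

test_that("weighted prevalence reduces to known arithmetic", {
  expect_equal(weighted_prevalence(c(1, 0), c(3, 1))$estimate, 0.75)
  wp <- weighted_prevalence(c(1, 1, 0, 0, 0), rep(2, 5))
  expect_equal(wp$estimate, 0.4)                      # equal weights = proportion
  expect_equal(wp$n_eff, 5)
  withr::with_seed(31, {
    f <- rbinom(10000, 1, 0.191)
    wp2 <- weighted_prevalence(f, rep(1, 10000))
    expect_lt(abs(wp2$estimate - 0.191), 0.012)
    expect_true(wp2$ci_low < 0.191 && wp2$ci_high > 0.191)
  })
  expect_error(weighted_prevalence(numeric(0), numeric(0)), "empty")
  expect_error(weighted_prevalence(c(1, 0), c(1, -1)), "weights")
})

test_that("chi-square test matches the direct Pearson formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, 2)
  res <- chi_square_test(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)   # independent oracle
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(sum((tab - E)^2 / E), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(res$p_value - 0.0098), 2e-4)

  prop <- matrix(c(10, 20, 20, 40), 2, 2)             # proportional rows
  expect_equal(chi_square_test(prop)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi_square_test(prop)$p_value, 1)

  expect_error(chi_square_test(matrix(c(0, 5, 0, 5), 2, 2)), "margin")
})

test_that("chi-square is invariant to row and column permutations", {
  withr::with_seed(2, {
    for (r in 1:5) {
      tab <- matrix(rpois(6, 20) + 1, 2, 3)
      s0 <- chi_square_test(tab)$statistic
      expect_equal(chi_square_test(tab[2:1, ])$statistic, s0, tolerance = 1e-10)
      expect_equal(chi_square_test(tab[, c(2, 1, 3)])$statistic, s0, tolerance = 1e-10)
    }
  })
})

test_that("Mann-Whitney U behaves like the enumerated statistic", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)  # all pairs reversed
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 9 / 2)                           # n1*n2/2 under identity
  expect_gt(same$p_value, 0.95)
  withr::with_seed(11, {
    x <- rnorm(500); y <- rnorm(500, 1)
    expect_lt(mann_whitney_u(x, y)$p_value, 0.001)
    # U(x,y) + U(y,x) = n1*n2, with ties present
    a <- round(rnorm(40), 1); b <- round(rnorm(30), 1)
    expect_equal(mann_whitney_u(a, b)$statistic + mann_whitney_u(b, a)$statistic,
                 40 * 30)
  })
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("the stratified descriptive table carries tests and both weightings", {
  d <- generate_dataset(synthetic_config(n_persons = 1500, weight_model = "gamma"),
                        seed = 4)
  tab <- describe_table(d, weights = "expansion_factor")
  expect_true(all(c("pct_total", "wpct_total", "median_obese", "p_value") %in% names(tab)))
  cats <- tab[tab$type == "categorical", ]
  expect_equal(sum(cats$pct_total[cats$variable == "sex"]), 100, tolerance = 1e-8)
  expect_equal(sum(cats$wpct_total[cats$variable == "wealth_quartile"]), 100,
               tolerance = 1e-8)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$variable[tab$type == "time"] %in%
                    c("computer_smartphone", "tv", "video_games",
                      "motor_vehicle", "cycling", "walking", "leisure_pa")))
})
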