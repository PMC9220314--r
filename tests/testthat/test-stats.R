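test_that("gated t-test: identical groups give t = 0, p = 1, no transform", {
  # normal-looking values so the assumption gate passes
  x <- c(9.2, 10.1, 10.8, 9.7, 10.4, 9.9, 10.6, 9.5, 10.2, 10.0)
  stopifnot(shapiro.test(x)$p.value > 0.05)
  res <- gated_t_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$transform, "none")
})

test_that("gated t-test is antisymmetric in its arguments", {
  set.seed(13)
  x <- rnorm(12, 10)
  y <- rnorm(12, 11)
  ab <- gated_t_test(x, y)
  ba <- gated_t_test(y, x)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
  expect_identical(ab$transform, ba$transform)
})

test_that("the log gate fires on strongly lognormal groups and is recorded", {
  set.seed(29)
  fired <- 0
  for (i in 1:20) {
    x <- rlnorm(20, 0, 1.5)
    y <- rlnorm(20, 0.5, 1.5)
    res <- suppressWarnings(gated_t_test(x, y))
    if (res$transform == "log") fired <- fired + 1
  }
  # heavy-tailed lognormal data should fail Shapiro-Wilk nearly always
  expect_gt(fired, 15)

  # log branch with non-positive values is refused with an offset hint
  set.seed(30)
  x <- c(rlnorm(15, 0, 2), -0.5)
  y <- rlnorm(16, 1, 2)
  expect_error(gated_t_test(x, y), "offset")
  expect_no_error(suppressWarnings(gated_t_test(x, y, offset = 1)))
})

test_that("rejection rate under a unit shift matches analytic t-test power", {
  # N(10,1) vs N(11,1), n = 15 per group; positive support keeps the
  # occasional log branch valid. Analytic power of the two-sample t-test
  # at this effect size is 0.753 (power.t.test); the gate rarely alters it.
  set.seed(59)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    res <- suppressWarnings(gated_t_test(rnorm(15, 10), rnorm(15, 11)))
    if (res$p_value < 0.05) rej <- rej + 1
  }
  analytic <- power.t.test(n = 15, delta = 1, sd = 1)$power
  expect_lt(abs(rej / n_rep - analytic), 0.07)  # ~3 binomial SE
})

test_that("welch flag switches the degrees of freedom", {
  set.seed(61)
  x <- rnorm(10, 50, 1)
  y <- rnorm(25, 50, 4)
  student <- suppressWarnings(gated_t_test(x, y))
  welch <- suppressWarnings(gated_t_test(x, y, welch = TRUE))
  expect_equal(student$df, 33)
  expect_lt(welch$df, 33)
})

test_that("OLS summary matches exact lines, flat data and the closed form", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  res <- suppressWarnings(ols_regression(d, y, x))  # exact fit warns
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)
  expect_equal(res$r2, 1, tolerance = 1e-12)

  flat <- tibble::tibble(x = 1:10, y = rep(3, 10))
  res_flat <- ols_regression(flat, y, x)
  expect_equal(res_flat$slope, 0)
  expect_equal(res_flat$r2, 0)
  expect_equal(res_flat$p_value, 1)

  set.seed(71)
  d2 <- tibble::tibble(x = rnorm(12, 5, 2), y = rnorm(12, 1, 3))
  res2 <- ols_regression(d2, y, x)
  orc <- oracle_ols(d2$x, d2$y)
  expect_equal(res2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(res2$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(res2$r2, orc$r2, tolerance = 1e-10)

  expect_error(ols_regression(tibble::tibble(x = rep(1, 5), y = 1:5), y, x),
               "[Dd]egenerate")
})

test_that("regression slope p and R2 are shift-equivariant", {
  set.seed(83)
  d <- tibble::tibble(x = rnorm(20, 100, 15), y = rnorm(20, 50, 5))
  base <- ols_regression(d, y, x)
  shifted <- ols_regression(dplyr::mutate(d, x = x + 1000, y = y - 77),
                            y, x)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-10)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-10)
  expect_equal(shifted$r2, base$r2, tolerance = 1e-10)
})
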