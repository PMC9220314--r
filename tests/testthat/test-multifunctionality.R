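test_that("Z-score standardization matches hand values and its identities", {
  fm <- tibble::tibble(plot_id = c("p1", "p2", "p3"), f = c(1, 2, 3))
  expect_equal(zscore_standardize(fm)$f, c(-1, 0, 1))

  fm2 <- tiny_function_matrix(n_plots = 12, n_fn = 4, seed = 3)
  sm <- zscore_standardize(fm2)
  for (fn in setdiff(names(sm), "plot_id")) {
    expect_lt(abs(mean(sm[[fn]])), 1e-10)
    expect_lt(abs(sd(sm[[fn]]) - 1), 1e-10)
  }
  expect_named(attr(sm, "center"), setdiff(names(fm2), "plot_id"))
})

test_that("constant functions error unless dropped explicitly", {
  fm <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
                       ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(zscore_standardize(fm), "flat")
  expect_warning(sm <- zscore_standardize(fm, drop_constant = TRUE), "flat")
  expect_named(sm, c("plot_id", "ok"))
})

test_that("averaging index: forced cases, zero grand mean, affine invariance", {
  sm <- tibble::tibble(plot_id = c("a", "b"), f1 = c(-1, 1), f2 = c(-1, 1))
  expect_equal(
    average_multifunctionality(sm, standardize = FALSE)$multifunctionality,
    c(-1, 1)
  )

  fm <- tiny_function_matrix(n_plots = 30, n_fn = 10, seed = 11)
  idx <- average_multifunctionality(fm)
  expect_lt(abs(sum(idx$multifunctionality)), 1e-10)

  # multiply a raw column by 7 and add 3: indices unchanged
  fm2 <- fm
  fm2$f3 <- 7 * fm2$f3 + 3
  idx2 <- average_multifunctionality(fm2)
  expect_equal(idx2$multifunctionality, idx$multifunctionality,
               tolerance = 1e-10)
})

test_that("function maxima use the mean of the top fraction", {
  fm <- tibble::tibble(plot_id = sprintf("p%d", 1:10), f = 1:10)
  expect_equal(function_maxima(fm, top_fraction = 1)$maximum, 5.5)
  # n = 10, top 5% -> ceiling(0.5) = 1 value -> the single largest
  expect_equal(function_maxima(fm, top_fraction = 0.05)$maximum, 10)
  expect_equal(function_maxima(fm, top_fraction = 0.25)$maximum,
               mean(c(10, 9, 8)))

  neg <- tibble::tibble(plot_id = c("p1", "p2", "p3"), Nm = c(-3, -1, -2))
  expect_error(function_maxima(neg), "Nm")
  shifted <- shift_nonnegative(neg)
  expect_equal(min(shifted$Nm), 0)
  expect_equal(function_maxima(shifted, top_fraction = 1)$maximum, 1)
})

test_that("single-threshold counts match forced examples and are monotone", {
  fm <- tibble::tibble(plot_id = "p1", f1 = 4, f2 = 1, f3 = 9)
  maxima <- tibble::tibble(fn = c("f1", "f2", "f3"), maximum = c(10, 10, 10))
  got <- single_threshold_counts(fm, maxima, thresholds = 0.5)
  expect_identical(got$n_functions, 1L)

  # plot at every function's maximum passes any threshold
  fm2 <- tiny_function_matrix(n_plots = 8, n_fn = 10, seed = 5)
  maxima2 <- function_maxima(fm2, top_fraction = 0.05)
  top_plot <- fm2[1, ]
  top_plot[-1] <- as.list(maxima2$maximum)
  got2 <- single_threshold_counts(top_plot, maxima2, thresholds = 0.9)
  expect_identical(got2$n_functions, 10L)

  counts <- single_threshold_counts(fm2, maxima2,
                                    thresholds = c(0.25, 0.9))
  wide <- tidyr::pivot_wider(counts, names_from = threshold,
                             values_from = n_functions)
  expect_true(all(wide$`0.25` >= wide$`0.9`))
})

test_that("threshold regression agrees with lm and the textbook formulas", {
  set.seed(42)
  x <- rnorm(10, 50, 10)
  y <- round(0.1 * x + rnorm(10))
  mine <- threshold_regression(y, x)
  fit <- summary(lm(y ~ x))
  expect_equal(mine$slope, unname(fit$coefficients["x", "Estimate"]),
               tolerance = 1e-12)
  expect_equal(mine$se, unname(fit$coefficients["x", "Std. Error"]),
               tolerance = 1e-12)
  expect_equal(mine$p, unname(fit$coefficients["x", "Pr(>|t|)"]),
               tolerance = 1e-12)
  expect_equal(mine$r2, fit$r.squared, tolerance = 1e-12)
  orc <- oracle_ols(x, y)
  expect_equal(mine$slope, orc$slope, tolerance = 1e-12)

  # exact line: slope recovered, p ~ 0, R2 = 1
  y2 <- 0.1 * x + 2
  exact <- threshold_regression(y2, x)
  expect_equal(exact$slope, 0.1, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  expect_lt(exact$p, 1e-12)

  # flat response: slope 0 with p = 1, not an error
  flat <- threshold_regression(rep(4, 10), x)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)

  expect_error(threshold_regression(y, rep(1, 10)), "[Dd]egenerate")
})

test_that("multiple-threshold analysis recovers a designed effect window", {
  # counts respond to richness at thresholds 10-40% and are flat elsewhere
  set.seed(99)
  n <- 30
  richness <- rnorm(n, 100, 20)
  grid <- 5:60
  counts <- matrix(0, n, length(grid))
  for (k in seq_along(grid)) {
    t <- grid[k]
    if (t >= 10 && t <= 40) {
      counts[, k] <- round(0.2 * richness + rnorm(n, 0, 2))
    } else {
      counts[, k] <- 5
    }
  }
  # feed pre-made counts through the regression layer directly
  fits <- purrr::map_dfr(seq_along(grid), function(k) {
    threshold_regression(counts[, k], richness)
  })
  sig <- which(fits$slope > 0 & fits$p < 0.05)
  t_min <- grid[sig[1]]
  expect_gte(t_min, 10)
  expect_lte(t_min, 40)
  i_mde <- which.max(fits$slope)
  expect_lt(abs(fits$slope[i_mde] - 0.2), 3 * fits$se[i_mde])
})

test_that("threshold curve object is internally consistent", {
  sim <- simulate_dataset(seed = 3)
  rich <- dplyr::rename(otu_richness(sim$otu_fungi), plot_id = "sample_id")
  tc <- multiple_threshold_analysis(sim$function_matrix, rich,
                                    domain = "fungi")
  curve <- tidy(tc)
  expect_identical(curve$threshold_pct, 5:99)
  g <- glance(tc)
  # r_mde is the maximum of the slope series, attained at t_mde
  expect_equal(g$r_mde, max(curve$slope))
  expect_equal(curve$slope[curve$threshold_pct == g$t_mde], g$r_mde)
  if (!is.na(g$t_min)) {
    row <- curve[curve$threshold_pct == g$t_min, ]
    expect_true(row$slope > 0 && row$p < tc$alpha)
    before <- curve[curve$threshold_pct < g$t_min, ]
    expect_false(any(before$slope > 0 & before$p < tc$alpha))
  }

  # a one-point grid forces t_mde onto that threshold
  tc1 <- multiple_threshold_analysis(sim$function_matrix, rich, grid = 50)
  expect_identical(tc1$t_mde, 50L)
  expect_equal(nrow(tidy(tc1)), 1)
})
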