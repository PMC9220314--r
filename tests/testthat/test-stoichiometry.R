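test_that("vector length matches closed-form values", {
  # symmetric case: both ln-ratios are 1 -> L = sqrt(2)
  e <- tibble::tibble(plot_id = "p1", bG = 100, NAG = 50, LAP = 50,
                      ALP = 100)
  expect_equal(vector_length(e)$vector_length, sqrt(2), tolerance = 1e-12)

  # frozen high-precision value for bG = 200, NAG + LAP = 100, ALP = 50
  e2 <- tibble::tibble(plot_id = "p1", bG = 200, NAG = 60, LAP = 40,
                       ALP = 50)
  expect_equal(vector_length(e2)$vector_length, 1.77707525593315713,
               tolerance = 1e-9)

  # bG -> 1+ drives L -> 0
  e3 <- tibble::tibble(plot_id = "p1", bG = 1 + 1e-9, NAG = 60, LAP = 40,
                       ALP = 50)
  expect_lt(vector_length(e3)$vector_length, 1e-8)

  # sqrt = FALSE returns the sum of squares (L^2)
  expect_equal(vector_length(e2, sqrt = FALSE)$vector_length,
               1.77707525593315713^2, tolerance = 1e-9)
})

test_that("vector length is strictly increasing in bG", {
  bg_grid <- seq(2, 500, length.out = 60)
  e <- tibble::tibble(plot_id = sprintf("p%d", seq_along(bg_grid)),
                      bG = bg_grid, NAG = 60, LAP = 40, ALP = 50)
  l <- vector_length(e)$vector_length
  expect_true(all(diff(l) > 0))
})

test_that("vector length enforces units and activity validity", {
  e <- tibble::tibble(plot_id = "p1", bG = 100, NAG = 50, LAP = 50,
                      ALP = 100)
  expect_error(vector_length(e, units = "umol_g_h"), "nmol_g_h")

  bad <- dplyr::mutate(e, bG = -1)
  expect_error(vector_length(bad), "p1")

  # denominator log argument <= 1 names the plot
  bad2 <- tibble::tibble(plot_id = c("ok", "bad"), bG = c(100, 100),
                         NAG = c(50, 0.4), LAP = c(50, 0.4),
                         ALP = c(100, 100))
  expect_error(vector_length(bad2), "bad")
})

test_that("the units sensitivity is real: rescaling activities changes L", {
  e <- tibble::tibble(plot_id = "p1", bG = 120, NAG = 60, LAP = 40,
                      ALP = 90)
  l_native <- vector_length(e)$vector_length
  rescaled <- dplyr::mutate(e, dplyr::across(c(bG, NAG, LAP, ALP),
                                             ~ .x * 1000))
  l_rescaled <- vector_length(rescaled)$vector_length
  expect_gt(abs(l_native - l_rescaled), 0.01)
})

test_that("C-limitation contrast: null case and designed-difference recovery", {
  vl0 <- tibble::tibble(plot_id = sprintf("p%d", 1:8),
                        vector_length = rep(1.3, 8))
  meta0 <- tibble::tibble(plot_id = sprintf("p%d", 1:8),
                          diversity_level = rep(c("low", "high"), each = 4))
  res0 <- compare_c_limitation(vl0, meta0)
  expect_equal(res0$difference, 0)
  expect_equal(res0$p_value, 1)

  # designed low - high difference of +0.5, sd 0.2, n = 15/15
  set.seed(77)
  vl <- tibble::tibble(
    plot_id = sprintf("p%d", 1:30),
    vector_length = c(rnorm(15, 1.8, 0.2), rnorm(15, 1.3, 0.2))
  )
  meta <- tibble::tibble(plot_id = sprintf("p%d", 1:30),
                         diversity_level = rep(c("low", "high"), each = 15))
  res <- suppressWarnings(compare_c_limitation(vl, meta))
  se_diff <- 0.2 * sqrt(2 / 15)
  expect_lt(abs(res$difference - 0.5), 3 * se_diff)
  expect_lt(res$p_value, 0.001)

  # a level with one plot is refused
  expect_error(
    compare_c_limitation(vl[c(1, 16:30), ], meta),
    ">= 2 plots"
  )
})
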