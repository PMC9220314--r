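#' Normality-gated two-sample t-test
#'
#' An independent-sample t-test preceded by an assumption gate: Shapiro-Wilk
#' normality tests on each group and a Bartlett test of variance homogeneity
#' across the two groups, all at `gate_alpha`. If any gate test fails, both
#' groups are natural-log transformed and the gate re-checked; the t-test is
#' then run on the (possibly transformed) data. The transform actually
#' applied is recorded in the result. If the gate still fails after the log
#' transform the test proceeds with a warning, since no further remedy is
#' defined.
#'
#' Student's equal-variance t-test is the default (the log transform, not
#' Welch's correction, being the designated remedy for heteroscedasticity);
#' set `welch = TRUE` for a sensitivity analysis.
#'
#' @param x,y Numeric vectors (each n >= 3).
#' @param gate_alpha Significance level of the gate tests (default 0.05).
#' @param welch Use Welch's unequal-variance t-test instead of Student's.
#' @param offset Constant added to both groups before the log transform, for
#'   data with non-positive values; the default 0 means non-positive values
#'   in the log branch are an error suggesting this argument.
#' @return One-row tibble of class `gated_t_test`: `mean_x`, `mean_y`
#'   (original-scale group means), `estimate` (difference of analysis-scale
#'   means), `statistic`, `df`, `p_value`, `transform` (`"none"` or
#'   `"log"`), `gate_passed`.
#' @examples
#' set.seed(1)
#' gated_t_test(rnorm(15), rnorm(15, mean = 1))
#' @export
gated_t_test <- function(x, y, gate_alpha = 0.05, welch = FALSE, offset = 0) {
  if (length(x) < 3 || length(y) < 3) {
    abort("Each group needs n >= 3 for the Shapiro-Wilk gate.")
  }
  if (anyNA(x) || anyNA(y)) abort("Missing values in groups.")

  gate <- function(a, b) {
    sw_a <- if (sd(a) == 0) 0 else shapiro.test(a)$p.value
    sw_b <- if (sd(b) == 0) 0 else shapiro.test(b)$p.value
    bt <- if (sd(a) == 0 || sd(b) == 0) 0 else {
      bartlett.test(list(a, b))$p.value
    }
    min(sw_a, sw_b, bt) >= gate_alpha
  }

  # identical degenerate groups: no variance, nothing to test
  if (sd(c(x, y)) == 0) {
    return(structure(
      tibble::tibble(mean_x = mean(x), mean_y = mean(y), estimate = 0,
                     statistic = 0, df = length(x) + length(y) - 2,
                     p_value = 1, transform = "none", gate_passed = TRUE),
      class = c("gated_t_test", "tbl_df", "tbl", "data.frame")))
  }

  transform <- "none"
  xa <- x
  ya <- y
  gate_ok <- gate(xa, ya)
  if (!gate_ok) {
    if (any(x + offset <= 0) || any(y + offset <= 0)) {
      abort(paste0("Log transform requested by the gate but values are not ",
                   "positive; supply a positive `offset` to shift both ",
                   "groups before the log."))
    }
    xa <- log(x + offset)
    ya <- log(y + offset)
    transform <- "log"
    gate_ok <- gate(xa, ya)
    if (!gate_ok) {
      warn(paste0("Assumption gate still fails after log transform; ",
                  "t-test run on log scale regardless."))
    }
  }
  tt <- t.test(xa, ya, var.equal = !welch)
  structure(
    tibble::tibble(
      mean_x = mean(x),
      mean_y = mean(y),
      estimate = mean(xa) - mean(ya),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      transform = transform,
      gate_passed = gate_ok
    ),
    class = c("gated_t_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Ordinary least squares regression summary
#'
#' Fits `response ~ predictor` by OLS (via [stats::lm()]) and returns the
#' compact summary used throughout the diversity-function analyses: slope,
#' intercept, R-squared, the two-sided p-value for the slope, and n.
#'
#' @param data A data frame.
#' @param response,predictor Unquoted column names.
#' @return One-row tibble: `slope`, `se`, `intercept`, `r2`, `p_value`, `n`,
#'   `response`, `predictor`.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' ols_regression(d, y, x)
#' @export
ols_regression <- function(data, response, predictor) {
  response <- rlang::ensym(response)
  predictor <- rlang::ensym(predictor)
  y <- rlang::eval_tidy(response, data)
  x <- rlang::eval_tidy(predictor, data)
  if (is.null(x) || is.null(y)) abort("Columns not found in `data`.")
  keep <- is.finite(x) & is.finite(y)
  if (anyNA(x) || anyNA(y) || !all(keep)) {
    abort("Missing or non-finite values in regression inputs.")
  }
  n <- length(x)
  if (n < 3) abort("Need n >= 3 for the regression.")
  if (sd(x) == 0) abort("Degenerate predictor: x is constant.")
  if (sd(y) == 0) {
    # flat response: slope 0, no explained variance
    return(tibble::tibble(
      slope = 0, se = 0, intercept = y[1], r2 = 0, p_value = 1, n = n,
      response = rlang::as_string(response),
      predictor = rlang::as_string(predictor)
    ))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  slope_p <- if (nrow(co) < 2 || is.na(co["x", "Pr(>|t|)"])) {
    1  # flat response: zero residual slope carries no evidence
  } else {
    co["x", "Pr(>|t|)"]
  }
  tibble::tibble(
    slope = unname(co["x", "Estimate"]),
    se = unname(co["x", "Std. Error"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    r2 = sm$r.squared,
    p_value = slope_p,
    n = n,
    response = rlang::as_string(response),
    predictor = rlang::as_string(predictor)
  )
}
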