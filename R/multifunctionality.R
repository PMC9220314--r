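#' Z-score standardize a function matrix
#'
#' Standardizes each function column to mean 0 and unit sample standard
#' deviation (n-1 denominator), the transformation underlying the averaging
#' multifunctionality index. The per-function centers and scales are retained
#' as attributes so the transform is invertible.
#'
#' @param fm Function matrix tibble (`plot_id` + numeric function columns).
#' @param drop_constant If `TRUE`, zero-variance functions are dropped with a
#'   warning instead of raising an error.
#' @return A tibble of the same shape with Z-scored function columns and
#'   attributes `center` and `scale` (named numeric vectors).
#' @examples
#' fm <- tibble::tibble(plot_id = c("p1", "p2", "p3"), bG = c(1, 2, 3))
#' zscore_standardize(fm)$bG  # -1, 0, 1
#' @export
zscore_standardize <- function(fm, drop_constant = FALSE) {
  validate_function_matrix(fm)
  fn_cols <- setdiff(names(fm), "plot_id")
  sds <- vapply(fm[fn_cols], sd, numeric(1))
  const <- fn_cols[sds == 0 | !is.finite(sds)]
  if (length(const) > 0) {
    if (!drop_constant) {
      abort(paste0("Zero-variance function column(s): ",
                   paste(const, collapse = ", "),
                   ". Use `drop_constant = TRUE` to exclude them."))
    }
    warn(paste0("Dropping zero-variance function(s): ",
                paste(const, collapse = ", ")))
    fn_cols <- setdiff(fn_cols, const)
    fm <- fm[c("plot_id", fn_cols)]
    sds <- sds[fn_cols]
  }
  if (length(fn_cols) == 0) abort("No non-constant function columns remain.")
  centers <- vapply(fm[fn_cols], mean, numeric(1))
  out <- fm
  for (fn in fn_cols) out[[fn]] <- (fm[[fn]] - centers[[fn]]) / sds[[fn]]
  attr(out, "center") <- centers
  attr(out, "scale") <- sds
  out
}

#' Averaging multifunctionality index
#'
#' The averaging approach: each function is Z-score standardized and the
#' per-plot multifunctionality index is the arithmetic mean of the plot's
#' Z-scores across functions. Because every Z-column has mean zero, the index
#' has grand mean zero across plots, and it is invariant to affine rescaling
#' of any raw function column.
#'
#' @param fm Function matrix on native scales (the default), or a matrix
#'   already carrying Z-scores, in which case use `standardize = FALSE` to
#'   average it as-is.
#' @param standardize Apply [zscore_standardize()] first (default `TRUE`).
#' @param drop_constant Passed to [zscore_standardize()].
#' @return A tibble with columns `plot_id` and `multifunctionality`.
#' @export
average_multifunctionality <- function(fm, standardize = TRUE,
                                       drop_constant = FALSE) {
  sm <- if (standardize) {
    zscore_standardize(fm, drop_constant = drop_constant)
  } else {
    validate_function_matrix(fm)
  }
  fn_cols <- setdiff(names(sm), "plot_id")
  tibble::tibble(
    plot_id = sm$plot_id,
    multifunctionality = rowMeans(as.matrix(sm[fn_cols]))
  )
}

#' Per-function reference maxima for threshold approaches
#'
#' The "maximum" of each function is taken as the mean of the top
#' `top_fraction` of its observed values (at least one value), the standard
#' convention in the threshold multifunctionality family, which damps the
#' influence of a single outlying plot. Thresholds are then set at a
#' percentage of this maximum.
#'
#' @param fm Function matrix on native scales.
#' @param top_fraction Fraction of observations averaged for the maximum,
#'   in (0, 1]; default 0.05 (top 5%).
#' @return A tibble with columns `fn` and `maximum`.
#' @section Negative-valued functions: thresholding against `t * maximum` is
#'   ill-posed when a function's maximum is not positive (possible for net N
#'   rates `Nn`/`Nm`). Such columns raise an error; use
#'   [shift_nonnegative()] first to subtract each function's observed
#'   minimum if you choose to threshold shifted values.
#' @export
function_maxima <- function(fm, top_fraction = 0.05) {
  validate_function_matrix(fm)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must be a single number in (0, 1].")
  }
  fn_cols <- setdiff(names(fm), "plot_id")
  n <- nrow(fm)
  k <- max(1L, ceiling(top_fraction * n))
  maxima <- vapply(fm[fn_cols], function(v) {
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
  nonpos <- fn_cols[maxima <= 0]
  if (length(nonpos) > 0) {
    abort(paste0("Non-positive maximum for function(s): ",
                 paste(nonpos, collapse = ", "),
                 ". Thresholding t * maximum is ill-posed; consider ",
                 "`shift_nonnegative()` before computing maxima."))
  }
  tibble::tibble(fn = fn_cols, maximum = unname(maxima))
}

#' Shift functions to non-negative range
#'
#' Subtracts each function's observed minimum so all values are >= 0. This is
#' an explicit, opt-in remedy for functions that can be negative (net
#' nitrification / N mineralization rates); it changes threshold counts and
#' must be reported alongside any result that uses it.
#'
#' @param fm Function matrix.
#' @return The shifted function matrix, with attribute `shifts` (the
#'   per-function minima that were subtracted).
#' @export
shift_nonnegative <- function(fm) {
  validate_function_matrix(fm)
  fn_cols <- setdiff(names(fm), "plot_id")
  mins <- vapply(fm[fn_cols], min, numeric(1))
  out <- fm
  for (fn in fn_cols) out[[fn]] <- fm[[fn]] - mins[[fn]]
  attr(out, "shifts") <- mins
  out
}

#' Single-threshold multifunctionality counts
#'
#' For each plot, counts the number of functions whose value meets or exceeds
#' `t * maximum` for threshold fraction(s) `t`. Counts are non-increasing in
#' `t` for every plot.
#'
#' @param fm Function matrix on native scales.
#' @param maxima Per-function maxima from [function_maxima()]; computed with
#'   defaults when omitted.
#' @param thresholds Numeric vector of threshold fractions in (0, 1), e.g.
#'   `c(0.25, 0.5, 0.75, 0.9)`.
#' @return A tibble with columns `plot_id`, `threshold`, `n_functions`
#'   (one row per plot x threshold).
#' @export
single_threshold_counts <- function(fm, maxima = NULL,
                                    thresholds = c(0.25, 0.5, 0.75, 0.9)) {
  validate_function_matrix(fm)
  if (is.null(maxima)) maxima <- function_maxima(fm)
  if (!all(c("fn", "maximum") %in% names(maxima))) {
    abort("`maxima` must have columns `fn` and `maximum` (see function_maxima()).")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("`thresholds` must lie strictly in (0, 1).")
  }
  fn_cols <- setdiff(names(fm), "plot_id")
  missing_fn <- setdiff(fn_cols, maxima$fn)
  if (length(missing_fn) > 0) {
    abort(paste0("`maxima` lacks function(s): ",
                 paste(missing_fn, collapse = ", ")))
  }
  mx <- setNames(maxima$maximum, maxima$fn)[fn_cols]
  vals <- as.matrix(fm[fn_cols])
  purrr::map_dfr(thresholds, function(t) {
    cut <- t * mx
    tibble::tibble(
      plot_id = fm$plot_id,
      threshold = t,
      n_functions = as.integer(rowSums(vals >= rep(cut, each = nrow(vals))))
    )
  })
}

#' OLS regression of threshold counts on richness
#'
#' Fits the number of functions above a threshold against microbial richness
#' by ordinary least squares, in closed form, and reports the slope (functions
#' per unit richness), its standard error, the two-sided p-value for slope
#' different from zero, the intercept, R-squared and n. When the counts are
#' constant the slope is 0 with p = 1 (a flat response, not an error).
#'
#' @param counts Numeric vector of per-plot function counts.
#' @param richness Numeric vector of per-plot richness, same length.
#' @return One-row tibble: `slope`, `se`, `p`, `intercept`, `r2`, `n`.
#' @export
threshold_regression <- function(counts, richness) {
  if (length(counts) != length(richness)) {
    abort("`counts` and `richness` must have equal length.")
  }
  n <- length(counts)
  if (n < 3) abort("Need >= 3 plots for the threshold regression.")
  if (anyNA(counts) || anyNA(richness)) abort("Missing values in inputs.")
  sxx <- sum((richness - mean(richness))^2)
  if (sxx == 0) abort("Degenerate predictor: richness is constant.")
  syy <- sum((counts - mean(counts))^2)
  sxy <- sum((richness - mean(richness)) * (counts - mean(counts)))
  slope <- sxy / sxx
  intercept <- mean(counts) - slope * mean(richness)
  sse <- max(0, syy - slope * sxy)
  if (syy == 0) {
    # constant response: flat line, no evidence either way
    return(tibble::tibble(slope = 0, se = 0, p = 1, intercept = intercept,
                          r2 = 0, n = n))
  }
  mse <- sse / (n - 2)
  se <- sqrt(mse / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0  # exact line
  } else {
    p <- 2 * pt(-abs(slope / se), df = n - 2)
  }
  tibble::tibble(slope = slope, se = se, p = p, intercept = intercept,
                 r2 = 1 - sse / syy, n = n)
}

#' Multiple-threshold multifunctionality analysis
#'
#' Runs the threshold-count regression across a full grid of threshold
#' fractions (default 5% to 99% of each function's maximum, step 1%) and
#' summarizes the resulting slope curve by three scalars:
#'
#' * `t_min` -- the minimum threshold (%) at which richness begins to have a
#'   significant positive effect (`slope > 0` and `p < alpha`); `NA` if no
#'   grid point qualifies.
#' * `t_mde` -- the threshold (%) of the maximum diversity effect, i.e. where
#'   the slope is largest (ties broken toward the smallest threshold).
#' * `r_mde` -- the realized maximum effect: the slope at `t_mde`, in
#'   functions per unit richness. (Also written "R_med" in parts of the
#'   literature; this package uses `r_mde` throughout.)
#'
#' @param fm Function matrix on native scales.
#' @param richness Per-plot richness: a numeric vector in plot order, or a
#'   data frame with columns `plot_id` and `richness` (joined by plot id).
#' @param grid Integer percentages for the threshold grid (default `5:99`).
#' @param alpha Significance level for the `t_min` rule (default 0.05).
#' @param top_fraction Passed to [function_maxima()].
#' @param shift_nonneg If `TRUE`, apply [shift_nonnegative()] before
#'   computing maxima and counts.
#' @param domain Optional label (e.g. `"fungi"`) carried into outputs.
#' @return A `threshold_curve` object; see [tidy.threshold_curve()] for the
#'   per-threshold table and [glance.threshold_curve()] for the scalars.
#' @examples
#' sim <- simulate_dataset(seed = 1)
#' curve <- multiple_threshold_analysis(
#'   sim$function_matrix,
#'   otu_richness(sim$otu_fungi) |> dplyr::rename(plot_id = sample_id),
#'   domain = "fungi"
#' )
#' glance(curve)
#' @export
multiple_threshold_analysis <- function(fm, richness, grid = 5:99,
                                        alpha = 0.05, top_fraction = 0.05,
                                        shift_nonneg = FALSE, domain = NULL) {
  validate_function_matrix(fm)
  if (is.data.frame(richness)) {
    if (!all(c("plot_id", "richness") %in% names(richness))) {
      abort("`richness` data frame needs columns `plot_id` and `richness`.")
    }
    missing_plots <- setdiff(fm$plot_id, richness$plot_id)
    if (length(missing_plots) > 0) {
      abort(paste0("No richness for plot(s): ",
                   paste(missing_plots, collapse = ", ")))
    }
    richness <- richness$richness[match(fm$plot_id, richness$plot_id)]
  }
  if (length(richness) != nrow(fm)) {
    abort("`richness` must have one value per plot.")
  }
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing.")
  if (any(grid <= 0 | grid >= 100)) abort("`grid` percentages must be in (0, 100).")
  if (shift_nonneg) fm <- shift_nonnegative(fm)
  maxima <- function_maxima(fm, top_fraction = top_fraction)
  counts <- single_threshold_counts(fm, maxima, thresholds = grid / 100)
  curve <- counts |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      threshold_regression(.data$n_functions, richness[match(.data$plot_id, fm$plot_id)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold_pct = as.integer(round(.data$threshold * 100)),
                  .before = 1)
  sig <- curve$slope > 0 & curve$p < alpha
  t_min <- if (any(sig)) curve$threshold_pct[which(sig)[1]] else NA_integer_
  i_mde <- which.max(curve$slope)  # which.max takes the first maximum: ties
  t_mde <- curve$threshold_pct[i_mde]  # break toward the smallest threshold
  structure(
    list(
      curve = curve,
      t_min = t_min,
      t_mde = t_mde,
      r_mde = curve$slope[i_mde],
      alpha = alpha,
      top_fraction = top_fraction,
      shift_nonneg = shift_nonneg,
      domain = domain
    ),
    class = "threshold_curve"
  )
}

#' @describeIn multiple_threshold_analysis Per-threshold regression table
#'   (`threshold_pct`, `threshold`, `slope`, `se`, `p`, `intercept`, `r2`, `n`).
#' @param x A `threshold_curve` object.
#' @param ... Unused.
#' @export
tidy.threshold_curve <- function(x, ...) {
  x$curve
}

#' @describeIn multiple_threshold_analysis One-row summary:
#'   `t_min`, `t_mde`, `r_mde` (plus `alpha`, `n_thresholds`, `domain`).
#' @export
glance.threshold_curve <- function(x, ...) {
  tibble::tibble(
    domain = x$domain %||% NA_character_,
    t_min = as.numeric(x$t_min),
    t_mde = as.numeric(x$t_mde),
    r_mde = x$r_mde,
    alpha = x$alpha,
    n_thresholds = nrow(x$curve)
  )
}

#' @export
print.threshold_curve <- function(x, ...) {
  dom <- if (!is.null(x$domain)) paste0(" [", x$domain, "]") else ""
  cat("Multiple-threshold multifunctionality analysis", dom, "\n", sep = "")
  cat("  grid: ", min(x$curve$threshold_pct), "-", max(x$curve$threshold_pct),
      "% (", nrow(x$curve), " thresholds), alpha = ", x$alpha, "\n", sep = "")
  if (is.na(x$t_min)) {
    cat("  T_min: not reached (no threshold with positive significant slope)\n")
  } else {
    cat("  T_min: ", x$t_min, "%\n", sep = "")
  }
  cat("  T_mde: ", x$t_mde, "%,  R_mde: ", signif(x$r_mde, 4),
      " functions per unit richness\n", sep = "")
  invisible(x)
}
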