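#' Enzymatic-stoichiometry vector length (microbial C limitation)
#'
#' Quantifies microbial carbon limitation from hydrolytic enzyme activities
#' as the Euclidean norm of two ln-ratio coordinates:
#'
#' \deqn{L = \sqrt{\left(\frac{\ln \beta G}{\ln(NAG + LAP)}\right)^2 +
#'                 \left(\frac{\ln \beta G}{\ln ALP}\right)^2}}
#'
#' where `bG` is beta-glucosidase (C acquisition), `NAG + LAP` the N
#' acquisition pair and `ALP` alkaline phosphatase (P acquisition). A longer
#' vector indicates stronger C limitation. Because ratios of logarithms are
#' not unit-invariant, activities must be supplied in nmol g^-1 h^-1 and the
#' `units` declaration is enforced.
#'
#' @param activities Data frame with columns `plot_id`, `bG`, `NAG`, `LAP`,
#'   `ALP` (a full function matrix works; extra columns are ignored).
#' @param units Unit declaration; must be `"nmol_g_h"`. This is deliberate
#'   friction: converting activities to another scale changes `L`.
#' @param sqrt Take the square root (Euclidean norm, default). `sqrt = FALSE`
#'   returns the sum of squared ln-ratios instead, i.e. `L^2`, for
#'   compatibility with reports that omit the radical.
#' @return A tibble with columns `plot_id` and `vector_length`.
#' @section Validity: all four activities must be positive, and the
#'   denominators must satisfy `NAG + LAP > 1` and `ALP > 1` so their
#'   logarithms are positive; violations raise an error naming the plot.
#'   `bG` values at or below 1 drive `L` toward 0 (weak C acquisition).
#' @examples
#' e <- tibble::tibble(plot_id = "p1", bG = 100, NAG = 50, LAP = 50, ALP = 100)
#' vector_length(e)$vector_length  # sqrt(2)
#' @export
vector_length <- function(activities, units = "nmol_g_h", sqrt = TRUE) {
  if (!identical(units, "nmol_g_h")) {
    abort(paste0("`units` must be declared as \"nmol_g_h\"; ln-ratio ",
                 "stoichiometry is not unit-invariant, so other scales are ",
                 "refused rather than silently rescaled."))
  }
  need <- c("plot_id", "bG", "NAG", "LAP", "ALP")
  missing <- setdiff(need, names(activities))
  if (length(missing) > 0) {
    abort(paste0("`activities` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  a <- activities[need]
  vals <- as.matrix(a[c("bG", "NAG", "LAP", "ALP")])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Enzyme activities must be finite and non-missing.")
  }
  nonpos <- rowSums(vals <= 0) > 0
  if (any(nonpos)) {
    abort(paste0("Non-positive enzyme activity in plot(s): ",
                 paste(a$plot_id[nonpos], collapse = ", ")))
  }
  n_den <- a$NAG + a$LAP
  bad_den <- n_den <= 1 | a$ALP <= 1
  if (any(bad_den)) {
    abort(paste0("Log denominator <= 0 (need NAG + LAP > 1 and ALP > 1) in ",
                 "plot(s): ", paste(a$plot_id[bad_den], collapse = ", ")))
  }
  l2 <- (log(a$bG) / log(n_den))^2 + (log(a$bG) / log(a$ALP))^2
  tibble::tibble(
    plot_id = a$plot_id,
    vector_length = if (sqrt) base::sqrt(l2) else l2
  )
}

#' Compare microbial C limitation between diversity levels
#'
#' Contrasts the vector length between the two diversity levels with the
#' normality-gated two-sample t-test ([gated_t_test()]). The reported
#' difference is low minus high, so a positive value means stronger C
#' limitation under low diversity.
#'
#' @param vl Tibble from [vector_length()] (`plot_id`, `vector_length`).
#' @param metadata Plot metadata with `plot_id` and a two-level
#'   `diversity_level` (see [read_plot_metadata()]).
#' @param ... Passed to [gated_t_test()] (e.g. `welch = TRUE`).
#' @return One-row tibble: `mean_low`, `mean_high`, `difference`
#'   (low - high), `statistic`, `df`, `p_value`, `transform`.
#' @export
compare_c_limitation <- function(vl, metadata, ...) {
  if (!all(c("plot_id", "vector_length") %in% names(vl))) {
    abort("`vl` needs columns `plot_id` and `vector_length`.")
  }
  if (!all(c("plot_id", "diversity_level") %in% names(metadata))) {
    abort("`metadata` needs columns `plot_id` and `diversity_level`.")
  }
  merged <- dplyr::inner_join(vl, metadata[c("plot_id", "diversity_level")],
                              by = "plot_id")
  levs <- levels(factor(merged$diversity_level))
  if (length(levs) != 2) {
    abort("`diversity_level` must have exactly two levels.")
  }
  lo_name <- if ("low" %in% levs) "low" else levs[1]
  hi_name <- setdiff(levs, lo_name)
  lo <- merged$vector_length[merged$diversity_level == lo_name]
  hi <- merged$vector_length[merged$diversity_level == hi_name]
  if (length(lo) < 2 || length(hi) < 2) {
    abort("Each diversity level needs >= 2 plots.")
  }
  tt <- gated_t_test(lo, hi, ...)
  tibble::tibble(
    mean_low = mean(lo),
    mean_high = mean(hi),
    difference = mean(lo) - mean(hi),
    statistic = tt$statistic,
    df = tt$df,
    p_value = tt$p_value,
    transform = tt$transform
  )
}
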