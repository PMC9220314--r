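# Independent oracles used across the suite. These re-derive expected values
# by a different route than the implementation and must stay that way.

# Literal six-predicate rarity classifier: each predicate written directly
# from its definition on the (min, max) relative-abundance profile, with the
# boundary conventions resolved by explicit precedence (abundant-side rules
# win at max == abundant threshold; AAT reads "abundant in all samples").
oracle_classify <- function(min_ra, max_ra, abundant = 0.01, rare = 1e-4) {
  is_aat <- min_ra >= abundant
  is_art <- max_ra < rare
  is_crat <- (min_ra < rare) & (max_ra >= abundant)
  is_cat <- (min_ra >= rare) & (max_ra >= abundant) & !is_aat
  is_crt <- (min_ra < rare) & (max_ra < abundant) & !is_art
  is_mt <- (min_ra >= rare) & (max_ra < abundant)
  out <- character(length(min_ra))
  out[is_mt] <- "MT"
  out[is_crt] <- "CRT"
  out[is_cat] <- "CAT"
  out[is_crat] <- "CRAT"
  out[is_art] <- "ART"
  out[is_aat] <- "AAT"
  stopifnot(all(out != ""))
  out
}

# Brute-force threshold counting: explicit double loop over plots and
# functions, no vectorization shared with the implementation.
oracle_threshold_counts <- function(values, maxima, t) {
  n_plots <- nrow(values)
  counts <- integer(n_plots)
  for (i in seq_len(n_plots)) {
    k <- 0L
    for (j in seq_len(ncol(values))) {
      if (values[i, j] >= t * maxima[j]) k <- k + 1L
    }
    counts[i] <- k
  }
  counts
}

# Textbook OLS formulas for the closed-form regression cross-checks.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  list(slope = slope, intercept = mean(y) - slope * mean(x), r2 = r2)
}

# Small fixture builders -----------------------------------------------------

tiny_function_matrix <- function(n_plots = 6, n_fn = 3, seed = 1) {
  set.seed(seed)
  fm <- tibble::tibble(plot_id = sprintf("p%d", seq_len(n_plots)))
  for (j in seq_len(n_fn)) {
    fm[[paste0("f", j)]] <- round(runif(n_plots, 1, 100), 3)
  }
  fm
}

tiny_otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  sample_ids <- sample_ids %||% sprintf("s%d", seq_len(nrow(counts)))
  otu_ids <- otu_ids %||% sprintf("OTU_%d", seq_len(ncol(counts)))
  out <- tibble::as_tibble(as.data.frame(counts, check.names = FALSE))
  names(out) <- otu_ids
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  tibble::add_column(out, sample_id = sample_ids, .before = 1)
}

`%||%` <- rlang::`%||%`
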