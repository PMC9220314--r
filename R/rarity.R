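#' Per-sample relative abundances
#'
#' Converts an OTU count table (canonical samples x OTUs orientation) into
#' row-normalized proportions. Every row sums to 1; proportions are the
#' metric on which the rarity classification operates, so multiplying a
#' sample's counts by any constant changes nothing downstream.
#'
#' @param otu OTU table tibble (`sample_id` + integer count columns).
#' @return A tibble of the same shape with proportions in place of counts.
#' @export
relative_abundance <- function(otu) {
  validate_otu_table(otu)
  m <- otu_matrix(otu)
  p <- m / rowSums(m)
  out <- tibble::as_tibble(as.data.frame(p, check.names = FALSE))
  tibble::add_column(out, sample_id = otu$sample_id, .before = 1)
}

#' Per-sample OTU richness
#'
#' The number of OTUs observed (count > 0) in each sample, the standard
#' richness accounting used for diversity-function regressions.
#'
#' @param otu OTU table tibble.
#' @return A tibble with columns `sample_id` and `richness` (integer).
#' @export
otu_richness <- function(otu) {
  validate_otu_table(otu)
  m <- otu_matrix(otu)
  tibble::tibble(
    sample_id = otu$sample_id,
    richness = as.integer(rowSums(m > 0))
  )
}

#' Six-category abundance-based rarity classification
#'
#' Classifies every OTU by its minimum and maximum relative abundance across
#' samples, using an abundant threshold (default 1%) and a rare threshold
#' (default 0.01%):
#'
#' * `AAT` always abundant: min >= abundant threshold in all samples.
#' * `ART` always rare: max < rare threshold in all samples.
#' * `CRAT` conditionally rare and abundant: min < rare threshold in some
#'   sample and max >= abundant threshold in some sample.
#' * `CAT` conditionally abundant: min >= rare threshold in all samples and
#'   max >= abundant threshold in some sample (but not always abundant).
#' * `CRT` conditionally rare: min < rare threshold in some sample and max
#'   below the abundant threshold in every sample.
#' * `MT` moderate: everything else, i.e. rare threshold <= min and
#'   max < abundant threshold.
#'
#' The rules are evaluated in the order above, which makes the six categories
#' a partition (each OTU lands in exactly one). At a maximum of exactly the
#' abundant threshold the abundant-side rules win (CRT and MT require a
#' strict `max < abundant`), keeping the boundary deterministic. The
#' supersets abundant = AAT + CAT and rare = ART + CRT are reported by
#' [glance.rarity_classification()].
#'
#' @param ra Relative-abundance tibble from [relative_abundance()]
#'   (rows must sum to 1).
#' @param abundant_threshold Abundant cut-off as a proportion (default 0.01,
#'   i.e. 1%).
#' @param rare_threshold Rare cut-off as a proportion (default 1e-4, i.e.
#'   0.01%); must be below `abundant_threshold`.
#' @param domain Optional label carried into outputs.
#' @return A `rarity_classification` object with a per-OTU table
#'   ([tidy.rarity_classification()]) and a per-category summary (`$summary`:
#'   `category`, `n_otus`, `otu_fraction_pct`, `abundance_fraction_pct`,
#'   fractions summing to 100%).
#' @examples
#' otu <- tibble::tibble(sample_id = c("s1", "s2"),
#'                       OTU_1 = c(960L, 900L), OTU_2 = c(40L, 100L))
#' classify_rarity(relative_abundance(otu))
#' @export
classify_rarity <- function(ra, abundant_threshold = 0.01,
                            rare_threshold = 1e-4, domain = NULL) {
  if (!is.data.frame(ra) || !"sample_id" %in% names(ra)) {
    abort("`ra` must be a relative-abundance tibble (see relative_abundance()).")
  }
  if (!(rare_threshold > 0 && rare_threshold < abundant_threshold &&
        abundant_threshold < 1)) {
    abort("Need 0 < rare_threshold < abundant_threshold < 1.")
  }
  m <- as.matrix(ra[setdiff(names(ra), "sample_id")])
  if (any(m < 0) || any(m > 1)) abort("Relative abundances must lie in [0, 1].")
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    abort("Rows of `ra` must sum to 1; pass counts through relative_abundance().")
  }
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  category <- dplyr::case_when(
    mins >= abundant_threshold ~ "AAT",
    maxs < rare_threshold ~ "ART",
    mins < rare_threshold & maxs >= abundant_threshold ~ "CRAT",
    mins >= rare_threshold & maxs >= abundant_threshold ~ "CAT",
    mins < rare_threshold & maxs < abundant_threshold ~ "CRT",
    .default = "MT"
  )
  per_otu <- tibble::tibble(
    otu_id = colnames(m),
    min_ra = unname(mins),
    max_ra = unname(maxs),
    mean_ra = unname(colMeans(m)),
    category = factor(category, levels = rarity_categories())
  )
  summary <- per_otu |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n_otus = dplyr::n(),
      otu_fraction_pct = 100 * dplyr::n() / nrow(per_otu),
      abundance_fraction_pct = 100 * sum(.data$mean_ra) / sum(per_otu$mean_ra),
      .groups = "drop"
    )
  structure(
    list(per_otu = per_otu, summary = summary,
         abundant_threshold = abundant_threshold,
         rare_threshold = rare_threshold, domain = domain),
    class = "rarity_classification"
  )
}

#' Category codes of the rarity classification
#'
#' @return Character vector: AAT, CAT, ART, CRT, MT, CRAT.
#' @export
rarity_categories <- function() c("AAT", "CAT", "ART", "CRT", "MT", "CRAT")

#' @describeIn classify_rarity Per-OTU table: `otu_id`, `min_ra`, `max_ra`,
#'   `mean_ra`, `category`.
#' @param x A `rarity_classification` object.
#' @param ... Unused.
#' @export
tidy.rarity_classification <- function(x, ...) {
  x$per_otu
}

#' @describeIn classify_rarity One-row summary with the abundant
#'   (AAT + CAT) and rare (ART + CRT) superset fractions, in percent.
#' @export
glance.rarity_classification <- function(x, ...) {
  s <- x$summary
  pick <- function(cats, col) sum(s[[col]][s$category %in% cats])
  tibble::tibble(
    domain = x$domain %||% NA_character_,
    n_otus = sum(s$n_otus),
    rare_otu_pct = pick(c("ART", "CRT"), "otu_fraction_pct"),
    rare_abundance_pct = pick(c("ART", "CRT"), "abundance_fraction_pct"),
    abundant_otu_pct = pick(c("AAT", "CAT"), "otu_fraction_pct"),
    abundant_abundance_pct = pick(c("AAT", "CAT"), "abundance_fraction_pct"),
    crat_otu_pct = pick("CRAT", "otu_fraction_pct"),
    crat_abundance_pct = pick("CRAT", "abundance_fraction_pct"),
    mt_otu_pct = pick("MT", "otu_fraction_pct"),
    mt_abundance_pct = pick("MT", "abundance_fraction_pct")
  )
}

#' @export
print.rarity_classification <- function(x, ...) {
  dom <- if (!is.null(x$domain)) paste0(" [", x$domain, "]") else ""
  cat("Rarity classification", dom, ": ", nrow(x$per_otu), " OTUs\n", sep = "")
  cat("  thresholds: abundant >= ", 100 * x$abundant_threshold,
      "%, rare < ", 100 * x$rare_threshold, "%\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Guild-level relative abundance
#'
#' Aggregates per-sample relative abundance by fungal trophic guild
#' (pathotroph / saprotroph / symbiotroph / unassigned). OTUs missing from
#' the guild map count as `unassigned`; map entries for OTUs absent from the
#' table are ignored with a warning. Guild shares sum to 1 per sample.
#'
#' @param otu OTU table tibble (typically the fungal domain).
#' @param guild_map Tibble with columns `otu_id`, `guild` (see
#'   [read_guild_map()]).
#' @return A long tibble: `sample_id`, `guild`, `rel_abundance`.
#' @export
guild_relative_abundance <- function(otu, guild_map) {
  validate_otu_table(otu)
  if (!all(c("otu_id", "guild") %in% names(guild_map))) {
    abort("`guild_map` needs columns `otu_id` and `guild`.")
  }
  bad <- setdiff(unique(guild_map$guild), guild_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown guild label(s): ", paste(bad, collapse = ", ")))
  }
  otu_ids <- setdiff(names(otu), "sample_id")
  extra <- setdiff(guild_map$otu_id, otu_ids)
  if (length(extra) > 0) {
    warn(paste0(length(extra), " guild-map OTU id(s) absent from the table ",
                "were ignored (e.g. ", extra[1], ")."))
  }
  lookup <- setNames(guild_map$guild, guild_map$otu_id)
  guilds <- unname(lookup[otu_ids])
  guilds[is.na(guilds)] <- "unassigned"
  ra <- relative_abundance(otu)
  ra |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "prop") |>
    dplyr::mutate(guild = factor(guilds[match(.data$otu_id, otu_ids)],
                                 levels = guild_levels())) |>
    dplyr::group_by(.data$sample_id, .data$guild, .drop = FALSE) |>
    dplyr::summarise(rel_abundance = sum(.data$prop), .groups = "drop")
}
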