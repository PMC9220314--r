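#' Simulation configuration for a study-shaped synthetic dataset
#'
#' Bundles every parameter of [simulate_dataset()] with defaults emulating a
#' two-diversity-level, multi-site grassland design: 6 sites x 5 plots, three
#' sites per diversity level, ten soil functions driven by a latent fungal
#' richness effect, per-level lognormal enzyme activities, and sample x OTU
#' count tables drawn as multinomial samples over a long-tailed lognormal
#' species-abundance distribution (SAD) with seeded abundance tiers so all
#' six rarity categories are populated in expectation.
#'
#' @param n_sites Number of sites (default 6).
#' @param plots_per_site Plots per site (default 5).
#' @param n_low_sites Number of sites at the low diversity level (default 3;
#'   the remainder are high).
#' @param richness Latent richness model per domain: for each of `fungi` and
#'   `bacteria`, a vector `c(low, high, sd)` of level means and the
#'   within-level standard deviation (in OTUs).
#' @param functions Function-response model: `names` (default the ten
#'   canonical functions), per-function positive `scale` factors giving
#'   realistic native magnitudes, and the shared structural parameters
#'   `baseline`, `slope` (response per fungal OTU) and noise `sigma`, so that
#'   function j in plot i is `scale_j * (baseline + slope * S_i + eps)` with
#'   `eps ~ N(0, sigma)`.
#' @param enzymes Stoichiometry-assay model: lognormal `meanlog` for
#'   `bG`, `NAG`, `LAP`, `ALP` per diversity level and a common `sdlog`.
#'   The default gives low-diversity plots higher beta-glucosidase, hence a
#'   longer C-limitation vector.
#' @param biomass Above-/below-ground biomass model (`agb_mean`, `agb_sd`,
#'   `bgb_mean`, `bgb_sd`, per level where vectors), designed so BGB:AGB is
#'   higher under high diversity.
#' @param otu OTU-table model: `n_otus` per domain, SAD parameters
#'   (`sad_meanlog`, `sad_sdlog`), sequencing `depth` per sample,
#'   `n_bloom` conditional bloomer OTUs (present, at high abundance, only in
#'   richer samples; these populate CRAT), `n_straddle` OTUs seeded near the
#'   abundant threshold (populating CAT), and `guild_effect`, the
#'   log-abundance tilt per standardized unit of richness applied to
#'   saprotroph (+) and pathotroph (-) OTUs in the fungal table.
#' @param guilds Guild-label probabilities for the fungal OTU pool; must sum
#'   to 1 over pathotroph / saprotroph / symbiotroph / unassigned.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(
    n_sites = 6,
    plots_per_site = 5,
    n_low_sites = 3,
    richness = list(
      fungi = c(low = 400, high = 500, sd = 30),
      bacteria = c(low = 900, high = 950, sd = 40)
    ),
    functions = list(
      names = soil_function_names(),
      scale = c(aG = 30, bG = 100, bX = 25, CBH = 20, LAP = 60, NAG = 50,
                Nn = 5, Nm = 8, ALP = 80, AP = 10),
      baseline = 1,
      slope = 0.01,
      sigma = 0.5
    ),
    enzymes = list(
      meanlog = list(
        low = c(bG = log(150), NAG = log(60), LAP = log(40), ALP = log(90)),
        high = c(bG = log(60), NAG = log(60), LAP = log(40), ALP = log(90))
      ),
      sdlog = 0.2
    ),
    biomass = list(
      agb_mean = c(low = 350, high = 300), agb_sd = 40,
      bgb_mean = c(low = 400, high = 700), bgb_sd = c(low = 80, high = 110)
    ),
    otu = list(
      n_otus = c(bacteria = 1852, fungi = 1325),
      sad_meanlog = 0, sad_sdlog = 2,
      depth = 50000,
      n_bloom = 5, n_straddle = 3,
      guild_effect = 0.4
    ),
    guilds = list(
      probs = c(pathotroph = 0.15, saprotroph = 0.35, symbiotroph = 0.10,
                unassigned = 0.40)
    )) {
  cfg <- list(n_sites = n_sites, plots_per_site = plots_per_site,
              n_low_sites = n_low_sites, richness = richness,
              functions = functions, enzymes = enzymes, biomass = biomass,
              otu = otu, guilds = guilds)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_sites < 2 || cfg$n_low_sites < 1 ||
      cfg$n_low_sites >= cfg$n_sites) {
    abort("Need n_sites >= 2 and 1 <= n_low_sites < n_sites.")
  }
  if (cfg$plots_per_site < 1) abort("plots_per_site must be >= 1.")
  for (dom in c("fungi", "bacteria")) {
    r <- cfg$richness[[dom]]
    if (is.null(r) || !all(c("low", "high", "sd") %in% names(r))) {
      abort(paste0("richness$", dom, " needs named entries low, high, sd."))
    }
    if (r[["sd"]] <= 0) abort("Richness sd must be positive.")
  }
  fn <- cfg$functions
  if (fn$sigma <= 0) abort("functions$sigma must be positive.")
  if (!setequal(names(fn$scale), fn$names)) {
    abort("functions$scale must be named by functions$names.")
  }
  if (any(fn$scale <= 0)) abort("functions$scale must be positive.")
  if (cfg$enzymes$sdlog <= 0) abort("enzymes$sdlog must be positive.")
  if (cfg$otu$depth < 1000) abort("otu$depth must be >= 1000.")
  p <- cfg$guilds$probs
  if (!setequal(names(p), guild_levels()) || abs(sum(p) - 1) > 1e-9 ||
      any(p < 0)) {
    abort("guilds$probs must be non-negative over the four guilds and sum to 1.")
  }
  invisible(cfg)
}

# Deterministic per-component substream seeds so adding a component never
# perturbs the draws of another.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483629)
}

#' Simulate a complete study-shaped dataset with known ground truth
#'
#' Generates every input the pipeline consumes -- a plot x function matrix, a
#' plot metadata table, bacterial and fungal OTU tables, a fungal guild map
#' and a stoichiometry enzyme-assay table -- from the design in a
#' [sim_config()], together with the ground truth needed to verify recovery:
#' per-plot latent richness, the per-function raw-scale slopes, the designed
#' C-limitation contrast and the designed guild effect signs.
#'
#' The generative model: latent richness `S` is drawn per plot around its
#' diversity-level mean; function j in plot i is
#' `scale_j * (baseline + slope * S_fungi(i) + eps_ij)`; OTU counts are a
#' multinomial sample of `depth` reads over a lognormal SAD truncated to the
#' plot's `S` most abundant pool OTUs (so richer plots expose more taxa),
#' with bloomer and straddler tiers seeded so that all six rarity categories
#' are populated in expectation; enzyme-assay activities are lognormal with
#' beta-glucosidase elevated under low diversity, so the C-limitation vector
#' is longer there; biomass gives high-diversity plots a larger BGB:AGB
#' ratio. All draws derive from `seed` through fixed per-component
#' substreams (base R Mersenne-Twister).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `smf_simulation`: `function_matrix`, `metadata`,
#'   `otu_bacteria`, `otu_fungi`, `guild_map`, `enzymes`, `ground_truth`,
#'   `config`, `seed`.
#' @examples
#' sim <- simulate_dataset(seed = 1)
#' dplyr::glimpse(sim$metadata)
#' @export
simulate_dataset <- function(config = sim_config(), seed = 42) {
  validate_sim_config(config)
  seed <- as.integer(seed)

  # -- design ----------------------------------------------------------------
  site_ids <- sprintf("S%d", seq_len(config$n_sites))
  level <- rep(c("low", "high"),
               c(config$n_low_sites, config$n_sites - config$n_low_sites))
  design <- tidyr::expand_grid(site = seq_len(config$n_sites),
                               plot = seq_len(config$plots_per_site))
  plots <- tibble::tibble(
    plot_id = sprintf("S%dP%d", design$site, design$plot),
    site_id = site_ids[design$site],
    diversity_level = factor(level[design$site], levels = c("low", "high"))
  )
  n_plots <- nrow(plots)

  # -- latent richness -------------------------------------------------------
  set.seed(substream_seed(seed, 1))
  latent <- function(dom) {
    r <- config$richness[[dom]]
    mu <- ifelse(plots$diversity_level == "low", r[["low"]], r[["high"]])
    pmax(50L, pmin(as.integer(config$otu$n_otus[[dom]]),
                   as.integer(round(rnorm(n_plots, mu, r[["sd"]])))))
  }
  s_fungi <- latent("fungi")
  s_bact <- latent("bacteria")

  # -- soil functions --------------------------------------------------------
  set.seed(substream_seed(seed, 2))
  fn <- config$functions
  fm <- tibble::tibble(plot_id = plots$plot_id)
  for (f in fn$names) {
    eps <- rnorm(n_plots, 0, fn$sigma)
    fm[[f]] <- fn$scale[[f]] * (fn$baseline + fn$slope * s_fungi + eps)
  }

  # -- enzyme assay for stoichiometry ----------------------------------------
  set.seed(substream_seed(seed, 3))
  ez <- config$enzymes
  enzymes <- tibble::tibble(plot_id = plots$plot_id)
  for (e in c("bG", "NAG", "LAP", "ALP")) {
    ml <- ifelse(plots$diversity_level == "low",
                 ez$meanlog$low[[e]], ez$meanlog$high[[e]])
    enzymes[[e]] <- rlnorm(n_plots, ml, ez$sdlog)
  }

  # -- biomass ---------------------------------------------------------------
  set.seed(substream_seed(seed, 4))
  bm <- config$biomass
  lev_chr <- as.character(plots$diversity_level)
  pick <- function(x) if (length(x) == 1) rep(x, n_plots) else unname(x[lev_chr])
  agb <- pmax(50, rnorm(n_plots, pick(bm$agb_mean), pick(bm$agb_sd)))
  bgb <- pmax(50, rnorm(n_plots, pick(bm$bgb_mean), pick(bm$bgb_sd)))
  metadata <- dplyr::mutate(plots, agb = agb, bgb = bgb,
                            bgb_agb_ratio = bgb / agb)

  # -- guild map (needed before the fungal table: guilds tilt abundances) ----
  set.seed(substream_seed(seed, 7))
  n_f <- as.integer(config$otu$n_otus[["fungi"]])
  fungal_ids <- sprintf("OTU_F%04d", seq_len(n_f))
  guild_lab <- sample(names(config$guilds$probs), n_f, replace = TRUE,
                      prob = config$guilds$probs)
  guild_map <- tibble::tibble(otu_id = fungal_ids, guild = guild_lab)

  # -- OTU tables ------------------------------------------------------------
  otu_fungi <- simulate_otu_counts(
    config, seed_k = substream_seed(seed, 5), otu_ids = fungal_ids,
    latent_richness = s_fungi, sample_ids = plots$plot_id,
    guild_tilt = c(saprotroph = 1, pathotroph = -1, symbiotroph = 0,
                   unassigned = 0)[guild_lab]
  )
  n_b <- as.integer(config$otu$n_otus[["bacteria"]])
  otu_bact <- simulate_otu_counts(
    config, seed_k = substream_seed(seed, 6),
    otu_ids = sprintf("OTU_B%04d", seq_len(n_b)),
    latent_richness = s_bact, sample_ids = plots$plot_id,
    guild_tilt = NULL
  )
  attr(otu_fungi, "domain") <- "fungi"
  attr(otu_bact, "domain") <- "bacteria"

  # -- ground truth ----------------------------------------------------------
  b_raw <- fn$scale[fn$names] * fn$slope
  sd_fn <- vapply(fm[fn$names], sd, numeric(1))
  med <- function(lv) setNames(exp(unlist(ez$meanlog[[lv]])),
                               names(ez$meanlog[[lv]]))
  vl_at <- function(a) {
    sqrt((log(a[["bG"]]) / log(a[["NAG"]] + a[["LAP"]]))^2 +
           (log(a[["bG"]]) / log(a[["ALP"]]))^2)
  }
  ground_truth <- list(
    plots = dplyr::mutate(plots, latent_richness_fungi = s_fungi,
                          latent_richness_bacteria = s_bact),
    b_raw = b_raw,
    slope = fn$slope,
    sigma = fn$sigma,
    # conditional expectation of the averaging-index-vs-latent-richness slope
    # given the realized per-function standard deviations
    design_index_slope = mean(b_raw / sd_fn),
    design_vl_difference = vl_at(med("low")) - vl_at(med("high")),
    design_bgb_agb_difference =
      bm$bgb_mean[["high"]] / bm$agb_mean[["high"]] -
      bm$bgb_mean[["low"]] / bm$agb_mean[["low"]],
    guild_effect_signs = c(pathotroph = -1, saprotroph = 1, symbiotroph = 0)
  )

  structure(
    list(function_matrix = fm, metadata = metadata, otu_bacteria = otu_bact,
         otu_fungi = otu_fungi, guild_map = guild_map, enzymes = enzymes,
         ground_truth = ground_truth, config = config, seed = seed),
    class = "smf_simulation"
  )
}

# Multinomial counts over a truncated lognormal SAD.
#
# Pool OTUs are ranked by decreasing SAD weight; plot i draws `depth` reads
# over its `S_i` top-ranked OTUs, so latent richness controls how much of the
# tail is exposed. The last `n_bloom` ids are conditional bloomers (high
# weight, present only in plots with above-median richness); the
# `n_straddle` before them sit just above the 1% abundant threshold.
simulate_otu_counts <- function(config, seed_k, otu_ids, latent_richness,
                                sample_ids, guild_tilt = NULL) {
  set.seed(seed_k)
  o <- config$otu
  n_otus <- length(otu_ids)
  n_bloom <- min(o$n_bloom, n_otus)
  n_straddle <- min(o$n_straddle, n_otus - n_bloom)
  n_regular <- n_otus - n_bloom - n_straddle
  if (n_regular < 10) abort("Too few OTUs for the tiered SAD model.")

  w_regular <- sort(rlnorm(n_regular, o$sad_meanlog, o$sad_sdlog),
                    decreasing = TRUE)
  w_straddle <- rep(0.0105 * sum(w_regular), n_straddle)
  w_bloom <- rep(0.02 * sum(w_regular), n_bloom)
  weights <- c(w_regular, w_straddle, w_bloom)

  bloom_on <- latent_richness >= stats::median(latent_richness)
  n_plots <- length(latent_richness)
  z <- as.numeric(scale(latent_richness))
  counts <- matrix(0L, nrow = n_plots, ncol = n_otus,
                   dimnames = list(sample_ids, otu_ids))
  for (i in seq_len(n_plots)) {
    s_i <- min(latent_richness[i], n_regular)
    avail <- seq_len(s_i)
    avail <- c(avail, n_regular + seq_len(n_straddle))
    if (bloom_on[i] && n_bloom > 0) {
      avail <- c(avail, n_regular + n_straddle + seq_len(n_bloom))
    }
    w_i <- weights[avail]
    if (!is.null(guild_tilt)) {
      w_i <- w_i * exp(o$guild_effect * z[i] * guild_tilt[avail])
    }
    counts[i, avail] <- rmultinom(1, o$depth, w_i / sum(w_i))[, 1]
  }
  out <- tibble::as_tibble(as.data.frame(counts, check.names = FALSE))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- tibble::add_column(out, sample_id = sample_ids, .before = 1)
  validate_otu_table(out)
  out
}

#' @export
print.smf_simulation <- function(x, ...) {
  cat("Synthetic soil-multifunctionality dataset (seed ", x$seed, ")\n",
      sep = "")
  cat("  ", nrow(x$metadata), " plots in ", x$config$n_sites, " sites (",
      sum(x$metadata$diversity_level == "low"), " low / ",
      sum(x$metadata$diversity_level == "high"), " high diversity)\n",
      sep = "")
  cat("  functions: ", ncol(x$function_matrix) - 1, "; OTUs: ",
      ncol(x$otu_bacteria) - 1, " bacterial, ",
      ncol(x$otu_fungi) - 1, " fungal; depth ", x$config$otu$depth,
      "\n", sep = "")
  invisible(x)
}

#' Construct an OTU table with known rarity-category tiers
#'
#' Builds a sample x OTU count table whose relative-abundance profiles are
#' placed analytically, with at least a 2x margin from the classification
#' thresholds, so that [classify_rarity()] must recover the requested
#' category for every seeded OTU. Used to test the classifier and as a
#' worked illustration of the six categories.
#'
#' Per category the profile across samples is (with `A` the abundant and `r`
#' the rare threshold, `hi = margin * A`, `lo = r / margin`, and `mid` the
#' geometric mean of the remaining safe band): AAT constant `hi`; ART
#' constant `lo`; MT constant `mid`; CAT `hi` in one sample, `mid`
#' elsewhere; CRT `lo` in one sample, `mid` elsewhere; CRAT `lo` in one
#' sample, `hi` in another, `mid` elsewhere. A filler OTU absorbs the
#' remaining reads in every sample (and is itself always abundant).
#'
#' @param tier_spec Named integer vector giving the number of OTUs to seed
#'   per category, e.g. `c(AAT = 10, MT = 10, ART = 100)`. Names must be
#'   among [rarity_categories()]; at least one entry must be positive.
#' @param n_samples Number of samples (>= 2; default 10).
#' @param depth Reads per sample. The smallest seeded proportion must be
#'   representable by at least 5 reads, otherwise an error reports the
#'   minimal sufficient depth.
#' @param abundant_threshold,rare_threshold Classifier thresholds the tiers
#'   are placed against.
#' @param margin Placement margin relative to the thresholds (default 2).
#' @return An OTU table tibble with attribute `expected_categories`, a
#'   tibble (`otu_id`, `expected_category`) covering the seeded OTUs and the
#'   filler.
#' @examples
#' otu <- simulate_rarity_fixture(c(AAT = 2, ART = 5, MT = 3), depth = 1e6)
#' cls <- classify_rarity(relative_abundance(otu))
#' @export
simulate_rarity_fixture <- function(tier_spec, n_samples = 10, depth = 1e6,
                                    abundant_threshold = 0.01,
                                    rare_threshold = 1e-4, margin = 2) {
  if (length(tier_spec) == 0 || is.null(names(tier_spec)) ||
      sum(tier_spec) == 0) {
    abort("`tier_spec` must be a non-empty named vector of OTU counts.")
  }
  bad <- setdiff(names(tier_spec), rarity_categories())
  if (length(bad) > 0) {
    abort(paste0("Unknown tier name(s): ", paste(bad, collapse = ", ")))
  }
  if (n_samples < 2) abort("Need n_samples >= 2 to realize conditional tiers.")
  A <- abundant_threshold
  r <- rare_threshold
  if (!(r > 0 && r < A && A < 1) || margin < 1) {
    abort("Need 0 < rare_threshold < abundant_threshold < 1 and margin >= 1.")
  }
  hi <- margin * A
  lo <- r / margin
  mid <- sqrt((A / margin) * (r * margin))  # geometric center of the safe band

  profile <- function(cat) {
    switch(cat,
      AAT = rep(hi, n_samples),
      ART = rep(lo, n_samples),
      MT = rep(mid, n_samples),
      CAT = c(hi, rep(mid, n_samples - 1)),
      CRT = c(lo, rep(mid, n_samples - 1)),
      CRAT = c(lo, hi, rep(mid, n_samples - 2))
    )
  }

  cats <- rep(names(tier_spec), tier_spec)
  p_min <- min(vapply(unique(cats), function(cat) min(profile(cat)),
                      numeric(1)))
  required_depth <- ceiling(5 / p_min)
  if (depth < required_depth) {
    abort(paste0("Depth ", depth, " cannot represent the smallest seeded ",
                 "relative abundance (", signif(p_min, 3), ") with at least ",
                 "5 reads; use depth >= ",
                 format(required_depth, scientific = FALSE), "."))
  }
  prof <- vapply(cats, profile, numeric(n_samples))  # samples x OTUs
  load <- rowSums(prof)
  if (any(load > 0.9)) {
    abort("tier_spec allocates > 90% of a sample's reads; reduce tier sizes.")
  }
  otu_ids <- sprintf("%s_%03d", cats, stats::ave(seq_along(cats), cats,
                                                 FUN = seq_along))
  counts <- round(prof * depth)
  filler <- depth - rowSums(counts)
  tbl <- cbind(counts, FILLER_001 = filler)
  colnames(tbl) <- c(otu_ids, "FILLER_001")
  out <- tibble::as_tibble(as.data.frame(tbl, check.names = FALSE))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  out <- tibble::add_column(out,
                            sample_id = sprintf("sample_%02d",
                                                seq_len(n_samples)),
                            .before = 1)
  validate_otu_table(out)
  attr(out, "expected_categories") <- tibble::tibble(
    otu_id = c(otu_ids, "FILLER_001"),
    expected_category = c(cats, "AAT")
  )
  out
}
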