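---
title: "Models and methods behind soilmultifun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind soilmultifun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilmultifun)
library(dplyr)
```

This vignette is the package's own account of the statistical machinery it
implements: the three multifunctionality quantifications, the six-category
rarity classifier, the enzymatic-stoichiometry vector length, the gated
comparison layer, and the synthetic study design used to verify all of
them. It also records the numerical conventions and the design choices that
were genuinely open.

## Multifunctionality

### The averaging index

Given a plot × function matrix on native scales, each function column is
Z-score standardized with the **sample (n − 1) standard deviation**, and
the per-plot index is the mean of the plot's Z-scores. Two identities
follow and are enforced by tests: every standardized column has mean 0 and
sd 1 (within 1e−10), so the index sums to zero across plots; and the index
is invariant under any affine rescaling of a raw function column, which is
what makes functions with incomparable units (nmol g⁻¹ h⁻¹ enzyme
activities, mg kg⁻¹ phosphorus, possibly negative N rates) averageable at
all.

Zero-variance columns make the Z-score undefined; they are a hard error by
default, with an explicit `drop_constant = TRUE` escape that excludes them
with a warning. Missing values are never imputed anywhere in the package —
plot-level soil datasets are small and complete, and silent imputation
would change every index downstream.

### Threshold counting

The single-threshold approach needs a per-function "maximum" to take
percentages of. A single observed maximum is fragile to one outlying plot,
so the package follows the standard convention in the threshold-family
literature: the **maximum is the mean of the top 5% of observed values**
(`top_fraction = 0.05`, i.e. the top ⌈0.05·n⌉ ≥ 1 values; configurable).
The count for plot i at threshold t is then
`#{j : x_ij ≥ t · max_j}`, which is non-increasing in t for every plot —
an invariant asserted on every run of the acceptance suite against a
brute-force double-loop oracle.

Thresholding against `t · max` is ill-posed when a maximum is not positive,
which can genuinely happen for net nitrification and N-mineralization
rates. The package refuses such columns loudly; `shift_nonnegative()`
subtracts each function's observed minimum as an explicit, opt-in remedy
that must be reported with any result using it. An additive shift is *not*
neutral for threshold counts (only multiplicative rescaling is), which is
exactly why it is not applied silently.

### The multiple-threshold curve

At every threshold of a grid (default 5–99% in steps of 1%, represented as
exact integer percentages so 16% is 0.16 and never 0.16000000001), the
count is regressed on microbial richness by OLS. The regression is computed
in closed form (slope, standard error, two-sided t-based p); tests verify
exact agreement with `lm()`, keeping the library fit available as an
independent oracle. A threshold where all counts are equal yields slope 0
with p = 1 — a flat response is evidence of nothing, not an error.

The curve is summarized by:

* **T_min** — the smallest grid threshold with slope > 0 *and* p < α
  (α = 0.05 by default). If no threshold qualifies, T_min is reported as
  missing rather than invented.
* **T_mde** — the grid threshold attaining the maximum slope; ties are
  broken toward the smallest threshold so the summary is deterministic.
* **R_mde** — the slope at T_mde (functions per unit richness). Parts of
  the literature typo this quantity as "R_med"; the package standardizes on
  `r_mde`.

Counts (not proportions of functions) are regressed, matching the
"number of functions" axis the summaries are defined on. A quasi-binomial
variant was considered and rejected as the default because the reported
effect size R_mde is defined in functions per added OTU, which is the OLS
slope's unit.

**A calibration caveat the package's own tests quantify:** declaring T_min
involves testing ~95 correlated thresholds at α = 0.05 each, with no
multiplicity control (none is defined for this summary). Under a true null
(richness permuted against functions), the family-wise chance of declaring
*some* T_min is therefore noticeably above α: across permutation runs the
suite measures T_min absent in only ≈ 85–87% of null runs, not ≥ 95%.
T_min near the edge of significance should be read accordingly.

## Rarity classification

Every OTU is classified from its minimum and maximum relative abundance
across samples, against an abundant threshold A = 1% and a rare threshold
r = 0.01%:

| order | category | rule |
|---|---|---|
| 1 | AAT | min ≥ A |
| 2 | ART | max < r |
| 3 | CRAT | min < r and max ≥ A |
| 4 | CAT | min ≥ r and max ≥ A |
| 5 | CRT | min < r and max < A |
| 6 | MT | otherwise (r ≤ min, max < A) |

Three boundary conventions make this a true partition, and they are the
package's explicit resolutions of ambiguities in how the categories are
usually phrased:

* "Always abundant" is read as abundant **in all samples** (min ≥ A);
  otherwise AAT would be a subset of CAT and the partition collapses.
* At max exactly A, the abundant-side rules win: CRT and MT require a
  strict max < A. An OTU peaking exactly at 1% is conditionally abundant,
  not conditionally rare.
* MT requires min ≥ r and max < A strictly, so MT and CAT cannot overlap.

The rules are evaluated in the order shown, and an independently written
predicate-based classifier (each category's definition coded literally,
with the same precedence) must agree on 10,000 randomized profiles in the
acceptance suite, including profiles pinned exactly at both thresholds.
Category summaries report each category's share of OTUs and of total
relative abundance (computed from per-OTU mean relative abundance, so both
columns sum to 100%). No rarefaction or depth normalization is applied
before classification: the classifier operates on per-sample relative
abundances as given, and is therefore invariant to per-sample count
scaling (asserted by test). Bacterial and fungal tables are always
classified separately.

## Enzymatic stoichiometry

The C-limitation statistic is the Euclidean norm of two ln-ratio
coordinates,
L = √((ln βG / ln(NAG + LAP))² + (ln βG / ln ALP)²).
The defining expression is sometimes printed without the radical; since a
*vector length* is a norm, the square root is taken here, and
`sqrt = FALSE` reproduces the literal sum of squares for comparison with
such reports.

Validity requires all activities positive and both denominators' log
arguments above 1 (else a denominator is ≤ 0); violations name the
offending plot. βG ≤ 1 is allowed — it drives L → 0, the no-C-acquisition
limit. Because ratios of logarithms are **not unit-invariant**, the
function refuses to run without the declared unit string `"nmol_g_h"`
(the scale of standard fluorometric assays); a test demonstrates that
rescaling activities by 10³ genuinely changes L. This is deliberate
friction: a silent unit conversion would silently change the statistic.

## The comparison layer

`gated_t_test()` implements the assumption-gated independent-sample t-test:
Shapiro–Wilk per group and Bartlett across the two groups, all at α = 0.05;
if any fails, both groups are natural-log transformed and the gate
re-checked; the t-test runs on the (possibly transformed) data with the
transform recorded in the result. Student's equal-variance test is the
default — the designated remedy for heteroscedasticity here is the log
transform, not Welch's correction — with `welch = TRUE` as a sensitivity
flag. If the gate still fails after the transform, the test proceeds with a
warning; no further remedy is defined. The gate is applied per group (not
to pooled residuals), and no multiple-testing correction is applied to the
reported p-values; both choices are documented rather than configurable
hidden state. Non-positive values in the log branch are an error that
points to the `offset` argument; the pipeline supplies an automatic offset
(1 − min) only for variables that are legitimately signed, such as the
averaging index, and the applied transform is always visible in the output.

Calibration is checked by simulation in the acceptance suite: under a null
of two identical normal populations the gated test rejects at a rate inside
[0.03, 0.07] over 2,000 replicates, and its power under a one-sd mean shift
at n = 15 per group matches the analytic `power.t.test()` value (≈ 0.75)
within binomial error.

## The synthetic study design

`simulate_dataset()` generates the package's verification universe: 6 sites
× 5 plots (30 plots), three sites per diversity level. Defaults were chosen
once, as a realistic semi-arid grassland scenario, and are not tuned to any
particular empirical result:

* **Latent richness** (OTUs): fungi N(400, 30²) under low diversity,
  N(500, 30²) under high; bacteria N(900, 40²) / N(950, 40²). Fungal
  richness is the functional driver; bacterial richness differs by level
  but does not drive functions, reproducing the asymmetry the analysis
  layer is meant to detect.
* **Functions**: `F_ij = c_j (1 + 0.01 · S_fungi(i) + ε_ij)`,
  ε ~ N(0, 0.5²), with per-function scales `c_j` giving realistic native
  magnitudes (e.g. βG around hundreds of nmol g⁻¹ h⁻¹). The multiplicative
  scale leaves Z-scores and threshold counts unchanged, so the structural
  slope 0.01 and noise 0.5 are the parameters that matter. The
  ground-truth object records the design-implied index slope
  `mean_j(c_j·0.01 / sd_j)` for the recovery test. Net N rates are kept
  positive in the default design so the threshold approaches stay
  well-posed out of the box.
* **OTU tables**: per sample, `depth = 50,000` reads drawn multinomially
  over a lognormal species-abundance distribution (meanlog 0, sdlog 2)
  truncated to the plot's S top-ranked pool OTUs — richer plots expose
  more of the tail, so observed richness tracks latent richness
  (correlation > 0.9 by test) while multinomial dropout keeps it noisy.
  Pool sizes are 1,852 bacterial and 1,325 fungal OTUs. Two seeded tiers
  guarantee the conditional categories exist in expectation: "bloomers"
  (weight ≈ 2% of the pool, present only in above-median-richness plots →
  CRAT) and "straddlers" (weight ≈ 1.05% in all plots, hovering at the
  abundant boundary → CAT). The lognormal tail makes rare taxa (ART + CRT)
  roughly three quarters of OTUs, the long-tailed structure typical of
  soil communities.
* **Guild effects**: fungal OTUs get guild labels with probabilities
  (pathotroph 0.15, saprotroph 0.35, symbiotroph 0.10, unassigned 0.40);
  saprotroph abundances are tilted up, and pathotroph down, by
  `exp(0.4 · z_i)` per standardized unit of plot richness, so saprotroph
  share correlates positively (and pathotroph negatively) with
  multifunctionality by construction.
* **Stoichiometry assay**: lognormal activities with βG elevated under low
  diversity (median 150 vs 60 nmol g⁻¹ h⁻¹, sdlog 0.2; N/P enzymes shared
  across levels), so the C-limitation vector is longer under low
  diversity by ≈ 0.29 at the medians. The enzyme-assay table is simulated
  separately from the function matrix: the assay carries the designed
  diversity contrast, while the function matrix's enzyme columns carry the
  richness response. A field dataset would have one measurement playing
  both roles.
* **Biomass**: AGB N(350, 40²) low / N(300, 40²) high, BGB N(400, 80²) /
  N(700, 110²), so BGB:AGB is designed higher under high diversity.

One global seed drives everything through fixed per-component substreams
(base R Mersenne–Twister), so adding a component never perturbs the draws
of another and the whole dataset is byte-reproducible.

What the generator deliberately does **not** emulate: sequence-level
artifacts (chimeras, clustering error), spatial autocorrelation between
plots, site-level random effects, compositional coupling between guilds
beyond the tilt, or mechanistic soil chemistry — latent richness drives
functions directly because the package tests statistics, not ecology.
Passing recovery tests therefore show that the estimators find effects of
the designed kind at realistic sizes; they do not validate the ecological
model itself on field data.

`simulate_rarity_fixture()` is the deterministic companion: it places
relative-abundance profiles analytically, at least 2× away from both
classification thresholds, so the classifier must recover the requested
category for every seeded OTU exactly; a filler OTU absorbs each sample's
remaining reads. The smallest seeded proportion must be representable by at
least 5 reads, otherwise the error names the minimal sufficient depth.

## Problem sizes and runtime choices

The verification suite uses 30-plot designs, 10,000-profile classifier
sweeps (200 tables × 50 OTUs), 100 random 30 × 10 matrices across the full
5–99% grid, 2,000-replicate type-I calibration and 200-permutation null
curves. These sizes give binomial/Monte-Carlo standard errors comfortably
below the asserted margins while keeping a full run in the low minutes on
one core.

## Known limitations

* The multiple-threshold summary has no multiplicity control (see the
  calibration caveat above); T_min is a descriptive scan, not a
  family-wise-controlled test.
* The vector-length statistic is unit- and scale-sensitive by
  construction; comparisons are only meaningful within one assay
  convention, which the API enforces but cannot verify.
* The gated t-test's log remedy changes the estimand (differences of log
  means); the `transform` field makes this visible but interpretation is
  the analyst's.
* Rarity categories depend on sequencing depth through the detection floor
  (1/depth); tables of very different depths should not be classified
  jointly, and the package does not rarefy for you.
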