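# soilmultifun

Quantitative tools for **biodiversity–ecosystem-function (BEF) analysis of
soils**: how does soil microbial diversity relate to the ability of a soil to
sustain many functions at once?

The package is aimed at soil ecologists and microbiome researchers who have
(i) a plot × function table of soil measurements (enzyme activities, N
cycling rates, available P), (ii) sample × OTU count tables for bacteria
and/or fungi, and (iii) plot metadata (site, plant-diversity level,
biomass). It implements the full quantitative chain linking them, plus a
synthetic-data generator emulating a multi-site, two-diversity-level
grassland design so every stage can be verified against known ground truth.

## What it computes

**Multifunctionality indices** over a default set of ten soil functions
(αG, βG, βX, CBH, LAP, NAG, Nn, Nm, ALP, AP — written `aG`, `bG`, … in
code):

* *Averaging*: each function Z-score standardized, the index is the per-plot
  mean of Z-scores, `SMF_i = (1/F) Σ_j z_ij`.
* *Single-threshold*: the number of functions with value ≥ t·max_j at fixed
  t (25/50/75/90% by default), where max_j is the mean of the top 5% of
  observed values of function j.
* *Multiple-threshold*: the single-threshold count regressed on microbial
  richness by OLS at every threshold t ∈ {5%, …, 99%}, summarized by
  **T_min** (smallest t with a significantly positive slope), **T_mde**
  (t of the maximum slope) and **R_mde** (that maximum slope, in functions
  per added OTU).

**Six-category OTU rarity classification** from each OTU's minimum and
maximum relative abundance across samples, with thresholds 1% (abundant)
and 0.01% (rare): AAT, CAT, ART, CRT, MT, CRAT, plus the abundant
(AAT ∪ CAT) and rare (ART ∪ CRT) supersets, with per-category shares of
OTUs and of total relative abundance.

**Enzymatic-stoichiometry vector length** quantifying microbial carbon
limitation:

```
L = sqrt( (ln βG / ln(NAG + LAP))² + (ln βG / ln ALP)² )
```

longer vectors mean stronger C limitation.

**Statistics layer**: independent-sample t-tests gated by Shapiro–Wilk and
Bartlett checks (with a natural-log remedy when the gate fails), and compact
OLS regression summaries (slope, R², p) for the richness / guild /
multifunctionality relationships. Fungal-guild (pathotroph / saprotroph /
symbiotroph) relative abundances are aggregated from an OTU → guild lookup
table.

## Worked example

```r
library(soilmultifun)
library(dplyr)

sim <- simulate_dataset(seed = 1)   # 30 plots, 6 sites, 2 diversity levels

# averaging multifunctionality vs observed fungal richness
smf  <- average_multifunctionality(sim$function_matrix)
rich <- rename(otu_richness(sim$otu_fungi), plot_id = sample_id)
d <- left_join(smf, rich, by = "plot_id")
ols_regression(d, multifunctionality, richness)
#>    slope       se intercept    r2  p_value     n response           predictor
#> 1 0.0126 0.000517     -5.83 0.955 2.09e-20    30 multifunctionality richness

# multiple-threshold analysis
curve <- multiple_threshold_analysis(sim$function_matrix, rich, domain = "fungi")
curve
#> Multiple-threshold multifunctionality analysis [fungi]
#>   grid: 5-99% (95 thresholds), alpha = 0.05
#>   T_min: 49%
#>   T_mde: 79%,  R_mde: 0.05866 functions per unit richness
autoplot(curve)

# rarity classification of the fungal community
cls <- classify_rarity(relative_abundance(sim$otu_fungi), domain = "fungi")
glance(cls)[, c("rare_otu_pct", "rare_abundance_pct")]
#>   rare_otu_pct rare_abundance_pct
#> 1         75.1               3.82

# microbial C limitation between diversity levels
vector_length(sim$enzymes) |> compare_c_limitation(sim$metadata)
#>   mean_low mean_high difference statistic df  p_value transform
#> 1     1.57      1.28      0.285      10.2  28 6.72e-11 none
```

The regression slope 0.0126 means each additional fungal OTU raises the
averaged multifunctionality index by about 0.013 standard-deviation units;
T_min = 49% is the lowest threshold at which richness significantly
increases the number of functions sustained, and R_mde = 0.059 is the
strongest such effect (at the 79% threshold). The positive vector-length
difference (low − high = 0.285, p < 0.001) shows the designed stronger C
limitation under low plant diversity being recovered.

`run_pipeline()` chains all stages from one YAML/list config and writes
per-stage TSVs plus a run log; with a fixed config and seed the outputs are
byte-identical across runs.

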