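# phytosdm

Ensemble species distribution modelling of global phytoplankton
diversity from biased presence-only occurrence data.

Open-ocean phytoplankton archives are presence-only, and their sampling
effort is extremely uneven — roughly half of all records can come from a
single basin. `phytosdm` implements the full diagnostic pipeline that
turns such records into monthly 1° maps of expected species richness and
month-to-month species turnover:

1. **Record cleaning and gridding** — fossil/preserved specimens, invalid
   years, depths and coordinates removed; records below the monthly
   climatological mixed layer dropped; open-ocean mask (bathymetry ≥
   200 m, salinity ≥ 20); binning to monthly 1° presences.
2. **Target-group background sampling** — pseudoabsences drawn from the
   pooled presences of a broad species group, stratified over a 9 × 9
   temperature × mixed-layer-depth grid (81 strata), 10 background points
   per presence, so background data inherit the presences' sampling bias.
3. **Predictor handling** — derived fields (N\*, Si\*, mixed-layer PAR,
   centred monthly trends, log transforms), single-predictor skill
   ranking (adjusted D², out-of-bag error), and randomised 5 × 4
   predictor sets with a |ρ| ≤ 0.7 within-set constraint and ≤ 2 reuses.
4. **SDM ensembles** — GLM (quadratic terms, stepwise AIC), GAM (5 basis
   dimensions) and random-forest (4000 trees, balanced subsampling)
   members; 4-fold split-sample cross-validation scored by the true
   skill statistic, TSS ≥ 0.35 retention, max-TSS binarisation, ensemble
   averaging to per-cell values in [0, 1].
5. **Diversity maps** — stacked (optionally taxon-balanced) richness,
   Jaccard-turnover-component maps over the 12 consecutive month pairs,
   and Monte Carlo uncertainty over predictor-set choice.
6. **Macroecology** — regressions of ln richness on inverse thermal
   energy `1/(kT)` globally and within thermal regimes (breakpoints 11
   and 19 °C), univariate explanatory-power tables, rarefied raw-data
   richness, species range-overlap curves and a label-shuffling null
   model with 95 % edge-effect flags.

The core quantitative claim this machinery addresses is the metabolic
theory of ecology: ln S should fall linearly with `1/(kT)` (k =
8.617×10⁻⁵ eV K⁻¹) with slope ≈ −0.32 eV. A built-in virtual-species
simulator generates environments, niches and biased samples with known
truth, so the whole pipeline is validated by parameter recovery rather
than by eyeballing maps.

## Worked example

```r
library(phytosdm)

g    <- grid_spec(40, 20, lat_min = -20, lon_min = 0)
env  <- derive_predictors(generate_environment(g, seed = 11))
pool <- generate_metabolic_pool(500, 0.32, env, seed = 12)
pipe <- run_sdm_pipeline(pool, env, n_samples = 500,
                         algorithm = "glm", seed = 13)
pipe
#> <sdm_pipeline> GLM: 500 species in pool, 434 modeled, 430 with ensembles
#>   44368 cleaned records, 43032 gridded presences

fit <- pipeline_metabolic_fit(pipe)
as.data.frame(fit)[, c("regime", "slope", "r_squared", "n")]
#>         regime       slope  r_squared   n
#> 1       global -0.31744286 0.94647191 716
#> 2       T < 11 -0.38721896 0.92664389 266
#> 3 11 <= T < 19 -0.39972428 0.83778620 201
#> 4      T >= 19 -0.05741764 0.08461214 249
attr(pool, "expected_slope")
#> [1] -0.3185503
```

A pool built with activation energy 0.32 eV has a true log-overlap slope
of −0.319 on this grid; the pipeline — after biased sampling, cleaning,
background correction, member fitting, retention and stacking — recovers
a global slope of −0.317. Per-regime rows show the same diagnostics the
regime analysis produces on real data (slope per eV, R², cell count).

## Command line

A thin wrapper over the same functions lives at `inst/cli/phytosdm.R`
(subcommands `simulate-env`, `simulate-pool`, `simulate-occ`, `prep`,
`thin`, `background`, `pipeline`); all interchange formats are plain CSV
(Darwin Core-style occurrence tables, long-format gridded climatologies
with a JSON header line).
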