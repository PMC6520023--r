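---
title: "Modelling global phytoplankton diversity from biased presence-only data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling global phytoplankton diversity from biased presence-only data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosdm)
```

## The problem

Open-ocean phytoplankton occurrence archives are presence-only and heavily
biased: sampling concentrates in a few basins and seasons, absences are
unobservable, and most species have few records. Mapping species richness
directly from such data confounds diversity with effort. `phytosdm`
implements the standard remedy at global scale: per-species ensembles of
species distribution models (SDMs) whose pseudoabsences inherit the
sampling bias of the presences, projected to monthly one-degree
climatologies, stacked into richness and species-turnover maps, and
analysed against the predictions of the metabolic theory of ecology.

Because no real archive carries ground truth, the package also contains a
virtual-species simulator. Every stage of the pipeline can therefore be
validated by parameter recovery: simulate species with known niches,
degrade them through biased sampling, and check that the pipeline's maps
and regressions recover the generative truth.

## The pipeline, stage by stage

**Cleaning and gridding.** Records flagged as fossil or preserved
specimens, with years outside 1800–2015, negative depths, or nonsensible
coordinates are removed; records deeper than the monthly climatological
mixed layer are removed, while records without a depth are kept only for
species otherwise observed inside the mixed layer. Cells shallower than
200 m or fresher than salinity 20 are excluded (open-ocean definition).
Surviving records are binned to monthly one-degree cells; repeat
observations of a species in the same cell and calendar month count as a
single presence. Each removed row is attributed to the first rule it
fails, so filter reports partition the input exactly.

**Background sampling.** For each species, pseudoabsences are drawn from a
*target group* — the pooled presence cells of a broad taxon set sampled by
the same community — so background data carry the same spatial and
seasonal bias as the presences. The target group's temperature and
mixed-layer-depth spans are each split into nine equal-width bins (81
strata); each stratum's quota is proportional to the number of
target-group cells it holds (largest-remainder rounding), sampling within
a stratum is uniform without replacement, the species' own presence cells
are excluded, and the total is ten times the species' presence count.
Sampling *without* replacement is a choice (the alternative is not
documented in the tradition this follows); exhausted strata redistribute
their deficit proportionally rather than silently under-sampling.

**Predictors.** Raw monthly climatologies (temperature, salinity,
nutrients, mixed-layer depth, PAR, chlorophyll, wind stress, pCO~2~) are
augmented with derived fields: excess nitrate `N* = NO3 − 16·PO4`, the
silicate ratio `Si* = SiOH4/NO3`, mixed-layer PAR with
chlorophyll-dependent attenuation `kd = 0.04 + 0.0088·Chl +
0.054·Chl^(2/3)` m⁻¹ (the attenuation function is replaceable through an
argument), centred month-to-month trends with December–January wrap (so
trends telescope to zero over a year), and base-10 logarithms of skewed
fields. Single-predictor skill tests rank candidates by adjusted D² (GLM,
GAM) and out-of-bag error (random forest, converted to `1 − OOB` so all
axes rank descending), averaging the three per-algorithm ranks.

**Member models and ensembles.** Five member models per species, each on a
different set of four predictors drawn at random from the species'
top-ranked candidates subject to two constraints: pairwise global Spearman
correlation at most 0.7 within a set, and each predictor in at most two of
the five sets. When the constraint graph is tight the search restarts with
fresh shuffles, relaxing the top-ten preference in the second half of the
restart budget; this keeps the procedure a randomised greedy draw, as
specified, while remaining solvable on small candidate lists. Members are
GLM (linear + quadratic terms, bidirectional stepwise AIC selection), GAM
(five basis dimensions per smooth) or random forest (4000 trees, terminal
node size 1, per-tree balanced background subsampling); GLM/GAM weight
background rows by the presence/background ratio so classes carry equal
weight. Skill is the mean true skill statistic (TSS) over a 4-fold
split-sample cross-validation, each fold scored on its held-out quarter
at the threshold that maximises TSS on the fold's training predictions
(picking the cut on the held-out data itself would bias skill upward by
about +0.05 on label-shuffled data, which the test suite checks);
members with TSS < 0.35 are discarded. The
deployed binarisation threshold is refit on the full calibration
predictions — the tradition separates evaluation from projection
thresholds without detail, and the full-data refit uses all information
available at deployment. Retained members are binarised (presence when
probability ≥ threshold; cells with missing predictors stay missing) and
averaged into an ensemble value in [0, 1] per monthly cell.

**Diversity maps and uncertainty.** Monthly richness is the (optionally
taxon-balanced) sum of ensemble values; the annual map is the mean over
covered months, with cells covered in fewer than 12 months flagged.
Species turnover uses the turnover (species-replacement) component of
Jaccard dissimilarity, `2·min(b,c)/(a + 2·min(b,c))`, on communities
defined by ensemble values strictly greater than 0.5, over the 12
consecutive month pairs including the December–January wrap (switchable;
the wrap is what makes exactly 12 pairs). Predictor-set uncertainty is
quantified by Monte Carlo: each run picks one retained member (one
predictor set) per species at random and recomputes the maps; because the
five members are already fitted, runs only resample projections, which is
what makes thousand-run designs cheap.

**Macroecology.** The Boltzmann-axis analysis regresses ln(annual-mean
richness) on inverse thermal energy `1/(kT)` (k = 8.617×10⁻⁵ eV K⁻¹, T in
kelvin), globally and within thermal regimes split at 11 and 19 °C
(defaults; a grid-search alternative over breakpoint pairs is provided for
sensitivity). Temperature matchup uses annual means of the monthly field.
Further tools: univariate explanatory power of each predictor for richness
(Gaussian linear + quadratic fits, R² for comparability across
predictors), rarefied raw-data richness by stratum, species' observed
environmental and latitudinal ranges, range-overlap richness curves, and a
randomisation null model that shuffles species labels across records
(conserving per-species record counts and the pooled environmental
distribution — the alternative reading, resampling locations, is not
implemented as the default but the shuffling unit is isolated in one
function). Edge effects are flagged where the null envelope's 95 %
interval excludes the envelope's own central-gradient level, the centre
being the middle 50 % of the observed span.

## The virtual world

The simulator produces an idealised two-hemisphere ocean: the grid's
central row acts as the equator, temperature declines linearly poleward
spanning −1.8 to 32 °C with a seasonal cycle whose amplitude peaks at
mid-latitudes (1 °C tropical, 4 °C mid-latitude by default, antiphase
between hemispheres), mixed layers deepen in winter, nitrate is
anticorrelated with temperature, phosphate tracks nitrate near the 16:1
ratio, and chlorophyll blooms seasonally at mid-latitudes. Chlorophyll,
mixed-layer depth and the Si:N ratio carry independent spatial structure;
without it every predictor collapses onto a single thermal axis,
cross-correlations all exceed 0.7, and the member-set constraints would be
unsatisfiable — real climatologies are decorrelated in the same way (the
tradition reports T–NO3 rank correlation around −0.7, not −1). A land
column, a shelf column (< 200 m) and a few brackish cells exercise the
masks consistently across months and variables.

Species carry Gaussian niches (product across predictors, scaled by a
maximum occurrence probability). Sampling effort is per-cell-per-month,
with 49 % of total intensity in one contiguous longitude block — a "north
Atlantic" analogue. The basin spans all latitudes so effort is biased in
space but balanced along the temperature gradient; that matters because
the pipeline can correct sampling bias but cannot resurrect species the
archive never sampled. Records inherit jittered coordinates, depths,
dates (years 1950–2000, mean 1984, SD 17), and small configurable
fractions of contaminated rows so the cleaning rules have work to do.

**Metabolic pools.** For recovery experiments the simulator builds pools
whose expected overlap count follows `ln S = c − E/(kT)` exactly: all
species share a fixed thermal range width (14 °C, within the observed
spread of phytoplankton thermal ranges), and range midpoints are drawn
from a density proportional to `exp(−E/(k·T))` over the temperature span
widened by half a range width on each side, so no edge truncation bends
the law. With this construction the expected-law slope deviates from −E by
less than 0.002 at the default width, and stratified inverse-transform
placement of midpoints keeps the realised slope's seed-to-seed SD near
3×10⁻⁴. The realised intercept `c` is returned so doubling the pool
demonstrably shifts `c` by ln 2 while leaving the slope untouched.

## Problem sizes and numerical choices

The recovery experiments run on a 40 × 20-cell grid (800 cells, 12
months), 500 species, 500 sampling events, and the GLM member algorithm —
the package's choices for a single-CPU desk-scale study. Two of these
choices deserve justification:

* **Sampling depth.** The ≥24-presence rule interacts with range
  truncation: species whose thermal range lies partly outside the
  temperature span have proportionally fewer attainable presences, and if
  the archive is shallow they drop below the modelling threshold *as a
  function of temperature*, deflating richness near the gradient ends and
  flattening the recovered Boltzmann slope. That is an under-sampling
  artifact, not a property of the method, and disappears when the
  simulated archive is deep enough that median presence counts sit near
  90. The defaults are set at that depth.
* **Algorithm.** The GLM member (quadratic logistic regression) is the
  correctly specified model for Gaussian niches — the log-odds of a
  Gaussian response are quadratic — and the only member cheap enough for
  five replicate worlds of 500 species, each needing 25 stepwise fits, on
  one CPU. Its stepwise search runs in compiled code and is tested for
  exact agreement with `stats::glm` deviances and with a pure-R reference
  implementation of the same search. GAM and random-forest members follow
  the same contracts and are exercised on smaller problems in the test
  suite. One intentional difference from `stats::step`: with non-integer
  case weights R's binomial AIC rounds weights inside the likelihood; the
  package uses `deviance + 2·p` with exact weights consistently (identical
  at unit weights).

Other numerical conventions: binarisation thresholds are chosen among the
unique predicted values (ties take the lowest); degenerate constant
predictions return that constant with TSS 0 and a warning; cross-validation
resplits with a fresh seed when a fold lacks a class, up to ten times;
IRLS caps at 12 iterations inside the stepwise search (quasi-separated
niche fits otherwise burn iterations refining coefficients that no longer
change selection); stratification bins include the maximum edge in the
ninth bin; quota rounding is largest-remainder so realised background
totals are exact when availability permits; all seeded stages restore the
caller's RNG state and are bit-reproducible.

## What the simulations do and do not show

Passing recovery tests show that the pipeline's bias correction,
evaluation, stacking and regression machinery are internally consistent
and recover known truth under the statistical structure the simulator
emulates: unimodal niches, monthly seasonality, strongly uneven but
temperature-balanced effort, and clean taxonomy. They do not show
robustness to features real archives have and the simulator does not:
taxonomic synonymy and misidentification, dispersal limitation, effort
biased *along* environmental gradients, abundance-dependent detectability,
or niches that are not unimodal in the modelled predictors. The open-ocean
analysis also inherits the SDM assumptions — species in equilibrium with
their environment and unlimited by dispersal — which are assumptions about
the ocean, not conclusions from these tests.

## Known limitations

* Effort is a single surface layer; depth structure of sampling is not
  emulated.
* The turnover map uses the replacement component only; nestedness is out
  of scope.
* Regime R² values are computed on cell-level data; the binned alternative
  is not implemented.
* The data-driven breakpoint search reports the SSE-minimising pair
  without inferential error bars (no segmented-regression standard
  errors).
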