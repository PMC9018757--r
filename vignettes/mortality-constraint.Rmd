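---
title: "Constraining projected forest carbon fluxes with observed tree mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraining projected forest carbon fluxes with observed tree mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(forestloss)
```

## The method in outline

Forests lose standing biomass when trees die. That flux — LOSS, in
Mg ha⁻¹ y⁻¹ of biomass per unit ground area — is one of the few carbon-cycle
quantities a field crew can measure essentially directly, by revisiting a
fixed plot and recording which stems died between censuses. At long time
scales and broad spatial scales LOSS, net primary productivity (NPP) and
heterotrophic respiration (HR) rise and fall together (faster growth, higher
mortality, faster decomposition), so a vegetation model whose historical
mortality is biased tends to carry that bias into its projected NPP and HR.
This package turns that coupling into an observational constraint, in five
stages.

**1. Screening.** Raw plot records pass through five criteria with the
defaults of `loss_screening_criteria()`: at least three censuses spanning
more than nine years (so LOSS averaged over the record reflects the stand,
not one interval); unmanaged and undisturbed; mature (age above 80 years in
boreal stands and 100 years in temperate ones, applied only where age is
recorded); quasi-steady state — neither growth nor LOSS more than three
times the other, since larger imbalances usually signal unrecorded
disturbance or regrowth; and biomass of at least 3 kg m⁻² to exclude stands
not yet fully stocked. Removed plots are attributed to the *first* criterion
they fail, in the order above, so the filter report reconciles counts
exactly; the order affects only attribution, never the surviving set (a plot
failing any criterion is out regardless). Two readings the criteria leave
open are fixed here: "three consecutive censuses" is read as a census count
of at least three, and the growth/LOSS band uses whole-record averages, with
the 0/0 case excluded under the same criterion (such a record carries no
usable rate information).

**2. Upscaling.** Surviving plots are averaged into 0.25° cells (half-open
cells, `[lon, lon+res) × [lat, lat+res)`, so a boundary plot lands in exactly
one cell; the cell value is the unweighted mean of its plots). Candidate
environmental covariates are pre-filtered: any pair with |r| > 0.7 loses the
member with the larger mean absolute correlation to the other covariates (a
deterministic tie-break), then covariates are removed greedily until every
variance-inflation factor is below 4. A random-forest regression
(`fit_upscaler`; 500 trees, √p candidate splits, unlimited depth — the
mapping model's hyperparameters are exposed because no canonical values
exist for them, unlike the surrogates below) is scored by 10-fold
cross-validation on pooled out-of-fold predictions and refit on all rows for
mapping. Model quality is summarised as CV R² together with its spread
across folds, following the rule that a good mapping model has high mean and
low spread; `max(CV R² − sd)` is the default selection rule when comparing
configurations. Cellwise uncertainty comes from two bootstrap schemes:
biome-stratified resampling preserving each biome's sample count (100
iterations) and random draws of 90% of rows with replacement (10
iterations); each yields an ensemble mean map and a CV map
(100·sd/mean, undefined where the mean is zero). Driver analyses use
permutation importance (%IncMSE: percent increase in MSE when one covariate
is permuted, averaged over 10 seeded permutations) and a linear mixed model
with a random intercept per plot, reporting coefficients per one standard
deviation of each predictor; with one row per plot the grouping is
unidentifiable and the function falls back to OLS with a warning. The stand
density index uses Reineke's form `SDI = N·(Dq/25.4)^1.605`; both constants
are arguments, since only "a function of tree density and quadratic mean
diameter" is canonical.

**3. Model–data comparison.** Model fields are analysed at 0.5°;
observation maps are regridded to match by area-weighted averaging of the
contributing fine cells (missing contributors are skipped and a coverage
fraction recorded — cells with partial coverage are retained, flagged, not
dropped). `compare_model_obs` reports the ensemble mean, the across-model
CV, and ΔLOSS = ensemble mean − observation.

**4. Conventional emergent constraint.** For one region,
`aggregate_for_ec` produces each member's historical-LOSS aggregate `x_i`
(averaged at plot locations, or area-weighted over region cells when a map
is used) and its projected flux sum `y_i` (Pg C y⁻¹). `fit_ec` is ordinary
least squares `y_i = a·x_i + b` across members. `constrain_ec` convolves the
regression's predictive distribution with the observed
`N(μ_obs, σ_obs²)`:

mean = a·μ_obs + b,
variance = s²(1 + 1/M + ((μ_obs − x̄)² + σ_obs²)/Σ(x_i − x̄)²) + a²σ_obs².

The σ_obs²/Σ(x_i − x̄)² term appears because the prediction-error variance
itself depends on x; including it makes the closed form the *exact* first
two moments of the convolution, which the test suite verifies against a
10⁶-draw Monte-Carlo integration. In plot-sites mode σ_obs defaults to the
standard error of the plot mean (the uncertainty of the regional mean, which
is what enters the regression), with the plot standard deviation available
via `sigma = "sd"`. When the slope is not significant (p > 0.05) the
constraint is still returned but flagged invalid with a warning — a weak
across-ensemble relationship cannot transmit observational information, and
this is exactly the regime where the grid-scale route below is preferable.

**5. Machine-learning constraint.** Per model and flux, `train_surrogate`
fits a random forest from the member's own historical LOSS (plus its
projected mean annual temperature and precipitation in the `"clim"`
scenario) to its projected flux at grid scale — 1000 trees, maximum depth
10, trained on a random 80% of forest cells and validated on the held-out
20%; these hyperparameters are fixed as part of the method. The
observational product (`build_loss_observation`) combines the two bootstrap
ensembles: overall mean = the average of the two ensemble means; overall
sd = 2·(sd₁ + sd₂) with sd_j = mean_j·CV_j/100 — a deliberately conservative
inflation standing in for uncertainty the bootstraps cannot see (the
covariate products themselves, for instance). A quadrature combination
`2·√(sd₁² + sd₂²)` is available behind `combine = "quadrature"`. One hundred
observation maps are then drawn per cell as independent Gaussians truncated
at zero (LOSS is non-negative); no spatial correlation model is imposed —
continental sums average over many cells, so cell-level independence mainly
understates the spread of the *sum*, which is conservative in the direction
that matters here. `apply_constraint` feeds each map through each surrogate,
aggregates constrained NPP and HR to continental sums, and computes the sink
as NEE = NPP − HR, an identity that holds exactly in the aggregates.
`compare_before_after` runs a one-way ANOVA per continent and flux; the
default pooling compares M model-level values against M model-level
bootstrap means, because pooling all model × map values inflates the sample
size and with it the apparent significance — the pooled mode is provided,
with that caveat attached.

Two unit conventions bridge observations and models. Biomass fluxes
(Mg ha⁻¹ y⁻¹) convert to carbon (gC m⁻² y⁻¹) in regional aggregation with a
configurable carbon fraction (default 0.5). The surrogates themselves are
unit-free in LOSS — each is trained within its own model's LOSS field — so
the observation map is standardized to the ensemble's LOSS units via
`loss_unit_scale` before feeding (1 for the synthetic ensemble, where both
sides are biomass). Whether model fluxes are masked to the observational
forest mask before continental sums is exposed through the `mask` argument
of the aggregation and constraint functions rather than hard-coded.

## The synthetic world

The generator exists so that every stage has recoverable ground truth; its
defaults are the package's study conditions and are not tuned per test.

* **Covariates** are Gaussian random fields (white noise smoothed by FFT
  convolution with a Gaussian kernel, circular boundaries, standardized),
  with mean annual temperature given a latitudinal gradient. Correlation
  length defaults to 6 cells.
* **True LOSS** is log-linear in standardized MAT, aridity and
  precipitation seasonality with coefficients 0.35/0.25/0.15 and median
  3.2 Mg ha⁻¹ y⁻¹, giving a 1.4–7 Mg ha⁻¹ y⁻¹ range over the domain —
  the right order for natural forests from boreal to wet tropical, and
  increasing in MAT and aridity so the driver analysis has a known sign
  structure to recover. The target of realism is this sign-and-magnitude
  structure, not any particular continent.
* **Plots**: 2676 by default (the scale of a real compiled network),
  clustered around 40 centres (real networks are national programmes, not
  uniform samples), at least three censuses spanning more than nine years,
  additive observation noise of 0.5 Mg ha⁻¹ y⁻¹ (roughly 15% of the mean),
  growth within ±30% of LOSS (quasi-steady), and — on request — exact
  planted fractions of violations of each screening criterion, recorded in
  a `planted` column so screening tests can assert exact recovery.
* **Ensemble**: six members at 0.5°. Member i's historical LOSS is the
  regridded truth plus its mean bias (default biases spanning −1.5 to
  +2.5 Mg ha⁻¹ y⁻¹, so the ensemble mean is biased high — the interesting
  case) plus a smooth member-specific bias field. Projected
  NPP = α_i + β_i·g(LOSS_his,i) + c·z(MAT_pro) + ε with β_i > 0 and g
  saturating (Michaelis–Menten with half-saturation 6 Mg ha⁻¹ y⁻¹) by
  default — the coupling is monotone but non-linear, which is precisely the
  regime the ML constraint claims over the linear EC; an identity link is
  available for EC-oriented tests. HR mirrors NPP with smaller
  coefficients, so NEE = NPP − HR is positive on average. The climate term
  (c = 40 gC m⁻² y⁻¹ per sd of MAT) makes the with-climate surrogate
  strictly more informative than the LOSS-only one, mirroring the observed
  ordering of surrogate validation skill (R ≈ 0.95 vs ≈ 0.98 on the
  defaults).

What the generator does *not* emulate: discrete disturbance events (fire,
insects) beyond flags, demographic age structure, spatially correlated
observation error, and model biases that change sign with time. Passing
tests therefore demonstrate that the machinery recovers planted structure
under these idealised conditions — not that real plot networks are unbiased
samples of real forests.

## The planted-bias experiment

`bias_recovery_experiment` is the package's end-to-end validation: every
ensemble member's historical LOSS is inflated by +30% (the bias pattern is
proportional to the true surface, so the bias is truly multiplicative),
observation maps are drawn around the *truth*, and the constraint should
pull the ensemble-mean projected NPP down from the unconstrained value
toward the truth-implied one while shrinking the across-model spread. The
with-climate surrogate scenario is the default here for an instructive
reason: in the no-climate scenario the surrogate learns
E[NPP | LOSS] *including* the climate share of NPP that covaries with LOSS,
so feeding lower LOSS also subtracts climate-attributed productivity and the
constrained value overshoots slightly below the truth-implied one.
Conditioning on projected climate isolates the LOSS pathway — the same
consideration that motivates including climate predictors in the surrogate
in the first place. The experiment runs 100 replicate seeds with 10
observation maps each in the acceptance suite (and 20 replicates in the
acceptance script); at these sizes the direction of the effect is stable in
100/100 replicates on the defaults.

## Numerical choices and degenerate inputs

* Cell areas use the spherical closed form `R²·Δλ·(sin φ_top − sin φ_b)`
  with R = 6 371 000 m; a global grid sums to 4πR² to 10⁻⁹ relative.
* Regridding is area-weighted for intensive variables, preserves the
  global area-weighted mean to 10⁻⁶ on gap-free grids, refines by
  replication, and errors on non-integer resolution ratios.
* Grids are cell-centre registered, latitude descending; regions are
  half-open box unions, checked for overlap; region totals skip missing
  cells and report coverage.
* Bootstrap CV maps set cells with zero mean to missing rather than
  dividing by zero; observation-map draws truncate at zero.
* The collinearity filter removes zero-variance covariates first and logs
  every removal with its trigger; its output provably satisfies both
  thresholds (asserted in tests).
* Screening on an empty table returns an empty table and an all-zero
  report; single-plot regions are flagged rather than given an SE;
  `fit_ec` refuses fewer than three members or zero variance in x.
* All generators and fitted models take explicit seeds; the same seed
  reproduces bit-identical worlds, plot tables, bootstrap draws, splits
  and forests.

## Problem sizes

The shipped tests and the acceptance script run on a 10° × 10° world at
0.25° (40 × 40 cells, ~1400 forested; 20 × 20 at the 0.5° model
resolution), plot networks of 300–2676, the full 100 + 10 bootstrap
iterations, 100 observation maps, and 100 replicate seeds for the
planted-bias experiment. These sizes were chosen so the full suite
exercises every code path at the documented iteration counts while
remaining comfortable to run repeatedly during development; the functions
themselves carry no size assumptions beyond their stated preconditions.

## Known limitations

* Box-union regions are a deliberate simplification; users with real
  continental polygons should supply their own membership masks.
* The EC implementation is the single-predictor Gaussian form; no
  hierarchical or multi-predictor variants.
* Surrogates use period-averaged fields only — no time dimension, no CO₂
  effects, single forcing scenario.
* The no-climate constraint inherits the LOSS–climate confounding
  discussed above; treat its point values accordingly and prefer the
  with-climate scenario when climate fields are available.
* Grid persistence is plain-text CSV with metadata headers; at global 0.5°
  scale these files are large, and a binary raster format through external
  tooling would be the practical choice.
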