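# forestloss

Constraining projected forest carbon fluxes with field-measured tree
mortality.

## The problem

Dynamic global vegetation models (DGVMs) disagree widely about how much
carbon forests will take up over the coming century. One reason is that
tree mortality — the rate at which standing biomass is lost when trees die,
here called **LOSS** (Mg ha⁻¹ y⁻¹) — is represented crudely in most models,
often as a fixed fraction of stocks, yet it is tightly coupled to growth:
across broad spatial scales, faster-growing forests lose biomass faster.
Because net primary productivity (NPP), heterotrophic respiration (HR) and
LOSS move together, a model that overstates historical mortality tends to
overstate projected productivity too. Unlike NPP or HR, LOSS can be
measured directly in repeatedly censused forest inventory plots, which
makes it a usable observational lever on projections.

`forestloss` implements that lever as a tested pipeline:

1. **Plot screening** — select largely unmanaged, mature, quasi-steady-state
   plot records by five criteria (≥3 censuses and >9-year span; unmanaged
   and undisturbed; mature, with age thresholds of 80/100 years in
   boreal/temperate stands; neither growth nor LOSS more than 3× the other;
   biomass ≥ 3 kg m⁻²), convert aboveground to total LOSS via the
   root–shoot ratio, and aggregate plots to a 0.25° observation grid.
2. **Upscaling** — a random-forest regression of gridded LOSS on
   environmental covariates (after pairwise-correlation and VIF
   pre-filtering), evaluated by 10-fold cross-validation, mapped over a
   natural-forest mask, with cellwise uncertainty from two bootstrap
   schemes (biome-stratified × 100; random 90% with replacement × 10) and
   driver analyses (permutation %IncMSE, linear-mixed-model coefficients,
   Reineke stand density index).
3. **Model–data comparison** — ensemble mean, across-model coefficient of
   variation, and the model-minus-observation ΔLOSS map at 0.5°.
4. **Conventional emergent constraint (EC)** — across an ensemble of M
   models, regress each member's projected continental flux on its
   historical LOSS aggregate, `y_i = a·x_i + b`, then convolve with the
   observed LOSS `N(μ_obs, σ_obs²)`; the constrained projection is
   `a·μ_obs + b` with variance combining regression prediction error and
   slope-scaled observational uncertainty.
5. **Machine-learning constraint** — per model, a random-forest surrogate
   `flux_pro = f(LOSS_his)` (optionally `f(LOSS_his, MAT_pro, MAP_pro)`)
   trained at grid scale (1000 trees, depth 10, 80/20 split), evaluated at
   100 bootstrap maps of observed LOSS drawn from the overall mean and a
   conservative overall standard deviation (2 × the summed bootstrap
   uncertainties); constrained NPP, HR and the net sink NEE = NPP − HR are
   aggregated per continent, with a before/after ANOVA.

Everything runs against a **synthetic world** (`generate_world`,
`sample_plots`, `simulate_ensemble`) with a known true LOSS surface,
a clustered censused plot network, and a model ensemble with configurable
LOSS biases and known LOSS→NPP/HR couplings — so every stage can be tested
against recoverable ground truth.

## Worked example

```r
library(forestloss)

world    <- generate_world(seed = 42)                 # 10° x 10° at 0.25°
plots    <- sample_plots(world, n = 1200,
                         violations = list(managed = 0.05,
                                           low_biomass = 0.05), seed = 43)
screened <- screen_plots(plots)
screened$report
#> Plot screening: 1200 in, 120 removed, 1080 surviving
#>                criterion removed
#>                 1_record       0
#>      2_managed_disturbed      60
#>               3_immature       0
#>  4_growth_loss_imbalance       0
#>            5_low_biomass      60   (planted managed / low-biomass plots)

obs <- aggregate_to_grid(screened$plots, 0.25, extent = world$extent)
tab <- filter_collinear(covariate_table(world, obs))$table
up  <- fit_upscaler(tab, k = 10, seed = 44)
up
#> <loss_upscaler> 6 covariates, 500 trees; CV R2 = 0.948 (fold sd 0.016),
#>                 fit R2 = 0.989
map <- predict_map(up, world$covariates, world$mask, world$grid)
cor(map$values[world$mask], world$loss_true[world$mask])
#> 0.991

ens  <- simulate_ensemble(world, coupling_spec(), seed = 45)
regs <- region_set(data.frame(region = "domain", lon_min = -180,
                              lon_max = 180, lat_min = -90, lat_max = 90))
ecin <- aggregate_for_ec(ens, "npp", regs, "domain",
                         mode = "plot-sites", plots = screened$plots)
fit  <- fit_ec(ecin$x, ecin$y)
fit
#> <ec_fit> M = 6: y = 0.1465 x + 0.2655, R2 = 0.998, p = 1.59e-06
constrain_ec(fit, ecin$mu_obs, ecin$sigma_obs)
#> <ec_constraint> 0.8768 +/- 0.01601 (unconstrained 0.9494 +/- 0.2242)
```

The cross-validated skill (CV R² = 0.95) says the covariates carry the LOSS
signal; the mapped surface correlates at 0.99 with the (here known) truth.
The EC fit shows a strong positive across-ensemble relationship between
historical LOSS and projected domain NPP (Pg C y⁻¹), and the observational
constraint both shifts the projection (0.95 → 0.88 Pg C y⁻¹ — this
synthetic ensemble's members are biased high on average) and collapses its
spread (0.22 → 0.016). The ML route (`train_surrogate`,
`build_loss_observation`, `apply_constraint`, `compare_before_after`) does
the same at grid scale without assuming linearity; see the methods
vignette.

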