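#' Synthetic world: covariate fields and a true mortality surface
#'
#' Generates a self-contained "world" for end-to-end testing of the
#' pipeline: smooth Gaussian-random-field covariates (mean annual
#' temperature, aridity index, precipitation seasonality, soil properties,
#' stand attributes), a strictly positive true LOSS surface that is a known
#' monotone increasing function of MAT and aridity (so the sign structure of
#' the driver analysis is recoverable), a tropical/temperate/boreal biome
#' classification, and a forest mask. Everything is deterministic given
#' `seed`.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param resolution grid resolution in degrees (default 0.25, the
#'   observation grid).
#' @param corr_len covariate correlation length, in cells.
#' @param loss_scale median of the LOSS surface (Mg ha-1 yr-1).
#' @param loss_coef named coefficients of the log-linear LOSS response to the
#'   standardized drivers; MAT and aridity must stay positive.
#' @param noise_sd sd of a multiplicative log-normal residual on the LOSS
#'   surface (0 = LOSS is exactly the stated function of covariates).
#' @param forest_fraction approximate fraction of cells that are forest.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_world`: list with `grid` (template
#'   `flux_grid`), `covariates` (named list of matrices), `loss_true`
#'   (matrix, Mg ha-1 yr-1), `biome` (character matrix), `mask`
#'   (`forest_mask`), and the generating parameters.
#' @export
generate_world <- function(extent = c(-70, -60, -15, -5), resolution = 0.25,
                           corr_len = 6, loss_scale = 3.2,
                           loss_coef = c(MAT = 0.35, aridity = 0.25,
                                         precip_seasonality = 0.15),
                           noise_sd = 0, forest_fraction = 0.85,
                           seed = 1) {
  if (resolution <= 0) stop("resolution must be positive")
  if (loss_coef[["MAT"]] <= 0 || loss_coef[["aridity"]] <= 0)
    stop("LOSS must increase with MAT and aridity")
  set.seed(seed)
  tmpl <- make_grid(extent, resolution, units = "Mg ha-1 yr-1",
                    variable = "LOSS")
  nlat <- length(tmpl$lat); nlon <- length(tmpl$lon)
  grf <- function() gaussian_field(nlat, nlon, corr_len)
  latm <- matrix(tmpl$lat, nlat, nlon)
  # covariates: climate + soil + stand structure, standardized copies used
  # for the LOSS response
  mat_raw <- 26 - 0.55 * abs(latm) + 4 * grf()
  covs <- list(
    MAT = mat_raw,
    aridity = pmax(0.05, 0.9 + 0.45 * grf() + 0.012 * (20 - abs(latm))),
    precip_seasonality = pmax(0, 40 + 18 * grf()),
    soil_N = pmax(0.02, 1.5 + 0.6 * grf()),
    CEC = pmax(1, 18 + 6 * grf()),
    clay = pmin(80, pmax(2, 28 + 10 * grf())),
    wood_density = pmin(0.9, pmax(0.3, 0.58 + 0.08 * grf())),
    tree_density = pmax(50, 600 + 220 * grf()),
    basal_area = pmax(5, 28 + 8 * grf()))
  # pmax/pmin against a scalar drop the dim attribute; restore matrix shape
  covs <- lapply(covs, function(m) matrix(m, nlat, nlon))
  z <- function(m) (m - mean(m)) / stats::sd(m)
  lin <- loss_coef[["MAT"]] * z(covs$MAT) +
    loss_coef[["aridity"]] * z(covs$aridity) +
    loss_coef[["precip_seasonality"]] * z(covs$precip_seasonality)
  loss <- loss_scale * exp(lin)
  if (noise_sd > 0)
    loss <- loss * exp(stats::rnorm(length(loss), 0, noise_sd))
  loss <- matrix(loss, nlat, nlon)
  # biome from MAT: tropical warm, boreal cold
  biome <- matrix("temperate", nlat, nlon)
  biome[covs$MAT >= 20] <- "tropical"
  biome[covs$MAT < 8] <- "boreal"
  mask_field <- grf()
  mask <- build_forest_mask(list(
    tree_cover = mask_field > stats::quantile(mask_field,
                                              1 - forest_fraction)))
  structure(list(grid = tmpl, covariates = covs, loss_true = loss,
                 biome = biome, mask = mask, resolution = resolution,
                 extent = extent, loss_scale = loss_scale,
                 loss_coef = loss_coef, noise_sd = noise_sd, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %dx%d cells at %.2f deg, ",
                     "%d covariates, %d forest cells\n"),
              nrow(x$loss_true), ncol(x$loss_true), x$resolution,
              length(x$covariates), sum(x$mask)))
  cat(sprintf("  true LOSS: %.2f .. %.2f Mg ha-1 yr-1\n",
              min(x$loss_true), max(x$loss_true)))
  invisible(x)
}

# smooth standardized Gaussian random field via FFT convolution of white
# noise with a Gaussian kernel (circular boundary; fine for synthetic use)
gaussian_field <- function(nlat, nlon, corr_len) {
  w <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  if (corr_len <= 0) return(w)
  di <- pmin(0:(nlat - 1), nlat - 0:(nlat - 1))
  dj <- pmin(0:(nlon - 1), nlon - 0:(nlon - 1))
  k <- exp(-(outer(di^2, dj^2, `+`)) / (2 * corr_len^2))
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    (nlat * nlon)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Sample a censused plot network from a synthetic world
#'
#' Draws `n` plot locations from the forested cells of a world, clustered
#' around a configurable number of cluster centres (emulating the uneven
#' geography of real inventory networks), and builds one plot record per
#' location: census dates (at least three, spanning more than nine years by
#' default), biomass, aboveground LOSS equal to the true surface at the
#' plot's cell plus Gaussian noise, growth in quasi-steady balance with
#' LOSS, stand attributes, and management/disturbance flags.
#'
#' A configurable fraction of plots is planted to violate each screening
#' criterion (short record, managed, immature, growth/LOSS imbalance, low
#' biomass); the planted criterion is recorded in the `planted` column so
#' screening tests can check exact recovery. Violation sets are disjoint.
#'
#' @param world a `synthetic_world`.
#' @param n number of plots.
#' @param n_clusters number of spatial cluster centres.
#' @param cluster_sd spatial scatter around each centre (degrees).
#' @param noise_sd sd of the additive observation noise on plot LOSS
#'   (Mg ha-1 yr-1).
#' @param violations named fractions in `[0, 1)` per criterion; names among
#'   `"record"`, `"managed"`, `"immature"`, `"imbalance"`, `"low_biomass"`.
#'   Counts are `round(fraction * n)` each.
#' @param seed integer RNG seed.
#' @return data.frame of plot records (one row per plot) with columns
#'   `plot_id`, `lon`, `lat`, `first_census`, `last_census`, `n_censuses`,
#'   `span`, `biomass`, `loss`, `growth`, `managed`, `disturbed`, `age`,
#'   `biome`, `tree_density`, `quadratic_mean_diameter`, `basal_area`,
#'   `wood_density`, `planted`.
#' @export
sample_plots <- function(world, n = 2676, n_clusters = 40, cluster_sd = 0.75,
                         noise_sd = 0.5, violations = NULL, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  g <- world$grid
  forest_idx <- which(world$mask)
  nlat <- length(g$lat)
  centers <- sample(forest_idx, min(n_clusters, length(forest_idx)))
  c_lat <- g$lat[(centers - 1) %% nlat + 1]
  c_lon <- g$lon[(centers - 1) %/% nlat + 1]
  if (any(c_lon < world$extent[1] | c_lon > world$extent[2]))
    stop("clustering kernel outside domain")
  pick <- sample(length(centers), n, replace = TRUE)
  lon <- c_lon[pick] + stats::rnorm(n, 0, cluster_sd)
  lat <- c_lat[pick] + stats::rnorm(n, 0, cluster_sd)
  lon <- pmin(pmax(lon, world$extent[1] + 1e-6), world$extent[2] - 1e-6)
  lat <- pmin(pmax(lat, world$extent[3] + 1e-6), world$extent[4] - 1e-6)
  ci <- cell_index(g, lon, lat)
  true_loss <- world$loss_true[ci]
  loss <- pmax(0.05, true_loss + stats::rnorm(n, 0, noise_sd))
  first <- round(stats::runif(n, 1951, 2000))
  n_cens <- sample(3:8, n, replace = TRUE)
  span <- round(stats::runif(n, 10, 40))
  growth <- loss * stats::runif(n, 0.75, 1.3)
  biome <- world$biome[ci]
  age <- ifelse(biome == "boreal", round(stats::runif(n, 90, 300)),
         ifelse(biome == "temperate", round(stats::runif(n, 110, 350)),
                NA_real_))
  plots <- data.frame(
    plot_id = sprintf("P%04d", seq_len(n)), lon = lon, lat = lat,
    first_census = first, last_census = first + span, n_censuses = n_cens,
    span = span,
    biomass = pmax(3.05, stats::rlnorm(n, log(12), 0.35)),
    loss = loss, growth = growth,
    managed = FALSE, disturbed = FALSE, age = age, biome = biome,
    tree_density = world$covariates$tree_density[ci],
    quadratic_mean_diameter = pmax(5, 24 + 6 * stats::rnorm(n)),
    basal_area = world$covariates$basal_area[ci],
    wood_density = world$covariates$wood_density[ci],
    true_loss = true_loss, planted = "none",
    stringsAsFactors = FALSE)
  if (!is.null(violations) && length(violations)) {
    known <- c("record", "managed", "immature", "imbalance", "low_biomass")
    bad <- setdiff(names(violations), known)
    if (length(bad)) stop("unknown violation type: ", paste(bad, collapse = ", "))
    counts <- vapply(violations, function(f) round(f * n), 0)
    if (sum(counts) > n) stop("violation fractions exceed the sample")
    pool <- sample(n)   # disjoint blocks
    off <- 0
    for (v in names(counts)) {
      idx <- pool[seq_len(counts[[v]]) + off]; off <- off + counts[[v]]
      if (!length(idx)) next
      plots$planted[idx] <- v
      if (v == "record") {
        half <- idx[seq_len(ceiling(length(idx) / 2))]
        plots$n_censuses[half] <- 2L
        short <- setdiff(idx, half)
        plots$span[short] <- round(stats::runif(length(short), 3, 9))
        plots$last_census[short] <- plots$first_census[short] +
          plots$span[short]
      } else if (v == "managed") {
        plots$managed[idx] <- TRUE
      } else if (v == "immature") {
        plots$biome[idx] <- sample(c("boreal", "temperate"), length(idx),
                                   replace = TRUE)
        plots$age[idx] <- ifelse(plots$biome[idx] == "boreal",
                                 round(stats::runif(length(idx), 20, 79)),
                                 round(stats::runif(length(idx), 20, 99)))
      } else if (v == "imbalance") {
        plots$growth[idx] <- plots$loss[idx] *
          sample(c(3.5, 0.2), length(idx), replace = TRUE)
      } else if (v == "low_biomass") {
        plots$biomass[idx] <- stats::runif(length(idx), 0.5, 2.9)
      }
    }
  }
  plots
}

# row/col -> single index of the cell containing each point (half-open cells)
cell_index <- function(grid, lon, lat) {
  res <- grid$resolution
  lon0 <- min(grid$lon) - res / 2
  lat1 <- max(grid$lat) + res / 2
  j <- floor((lon - lon0) / res) + 1
  i <- floor((lat1 - lat) / res) + 1
  if (any(j < 1 | j > length(grid$lon) | i < 1 | i > length(grid$lat)))
    stop("coordinates outside the grid domain")
  cbind(i, j)
}

#' Per-model coupling between historical LOSS and projected fluxes
#'
#' Defines how each synthetic ensemble member's projected NPP and HR depend
#' on its own (biased) historical LOSS: `flux = alpha_i + beta_i * g(LOSS) +
#' climate term + noise`, with `beta_i > 0` (faster growth, higher
#' mortality) and `g` either the identity or a saturating Michaelis-Menten
#' link `g(L) = L * K / (K + L)`.
#'
#' @param n_models ensemble size.
#' @param alpha_npp,beta_npp,alpha_hr,beta_hr per-model intercepts and
#'   slopes (gC m-2 yr-1, and per Mg ha-1 yr-1 of transformed LOSS);
#'   recycled to `n_models`. All `beta` must be positive.
#' @param link `"saturating"` (default) or `"identity"`.
#' @param K half-saturation constant of the saturating link (Mg ha-1 yr-1).
#' @param climate_effect sd-scale contribution of projected MAT to NPP/HR
#'   (gC m-2 yr-1 per sd of MAT); makes the with-climate surrogate strictly
#'   more informative than the LOSS-only one.
#' @param noise_sd sd of the residual flux noise (gC m-2 yr-1).
#' @param bias per-model mean LOSS bias (Mg ha-1 yr-1), recycled; each
#'   member's historical LOSS is the truth plus this bias plus a smooth
#'   spatial bias field.
#' @param bias_field_sd sd of the smooth per-model spatial bias component.
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(n_models = 6,
                          alpha_npp = seq(500, 750, length.out = n_models),
                          beta_npp = seq(90, 150, length.out = n_models),
                          alpha_hr = seq(380, 560, length.out = n_models),
                          beta_hr = seq(70, 115, length.out = n_models),
                          link = c("saturating", "identity"), K = 6,
                          climate_effect = 40, noise_sd = 20,
                          bias = seq(-1.5, 2.5, length.out = n_models),
                          bias_field_sd = 0.4) {
  link <- match.arg(link)
  if (n_models < 2) stop("n_models must be >= 2")
  rec <- function(x) rep_len(x, n_models)
  beta_npp <- rec(beta_npp); beta_hr <- rec(beta_hr)
  if (any(beta_npp <= 0) || any(beta_hr <= 0))
    stop("all beta must be positive (growth-mortality coupling)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_models = n_models, alpha_npp = rec(alpha_npp),
                 beta_npp = beta_npp, alpha_hr = rec(alpha_hr),
                 beta_hr = beta_hr, link = link, K = K,
                 climate_effect = climate_effect, noise_sd = noise_sd,
                 bias = rec(bias), bias_field_sd = bias_field_sd),
            class = "coupling_spec")
}

coupling_link <- function(spec, loss) {
  if (spec$link == "identity") loss else loss * spec$K / (spec$K + loss)
}

#' Simulate a model ensemble with known LOSS couplings
#'
#' Builds `n_models` ensemble members on a 0.5-degree grid (mirroring the
#' convention that model output is analysed at 0.5 degree while observations
#' live at 0.25): each member's historical LOSS is the regridded true
#' surface plus its configured bias, and its projected NPP and HR follow the
#' coupling in `spec` evaluated on its *own* historical LOSS, plus a climate
#' term and noise. Projected MAT/MAP fields are included for the
#' with-climate surrogate scenario.
#'
#' @param world a `synthetic_world`.
#' @param coupling a `coupling_spec`.
#' @param model_resolution analysis resolution for model fields (degrees).
#' @param bias_pattern optional matrix (model-grid shape) scaling each
#'   member's mean LOSS bias cell by cell (default 1 everywhere); lets a
#'   bias change sign between regions to study spatial compensation.
#' @param seed integer RNG seed.
#' @return object of class `model_ensemble`: list of `model_fields`, each
#'   with `name` and `flux_grid`s `loss_his` (1961-2014), `npp_pro`,
#'   `hr_pro` (2015-2099), `mat_pro`, `map_pro`; plus the shared `mask`,
#'   `truth` (true LOSS at model resolution) and the coupling.
#' @export
simulate_ensemble <- function(world, coupling = coupling_spec(),
                              model_resolution = 0.5, bias_pattern = NULL,
                              seed = 1) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(coupling, "coupling_spec"))
  set.seed(seed)
  truth25 <- flux_grid(world$loss_true, world$grid$lat, world$grid$lon,
                       units = "Mg ha-1 yr-1", variable = "LOSS")
  truth <- regrid(truth25, model_resolution)
  mask25 <- flux_grid(matrix(as.numeric(world$mask),
                             nrow(world$loss_true)), world$grid$lat,
                      world$grid$lon, units = "1", variable = "mask")
  mask <- regrid(mask25, model_resolution)$values >= 0.5
  mat <- regrid(flux_grid(world$covariates$MAT, world$grid$lat,
                          world$grid$lon, units = "degC",
                          variable = "MAT"), model_resolution)
  nlat <- length(truth$lat); nlon <- length(truth$lon)
  mat_pro_base <- mat$values + 3           # uniform projected warming
  map_pro_base <- matrix(pmax(200, 1500 + 500 *
                                gaussian_field(nlat, nlon, 4)), nlat, nlon)
  zmat <- (mat_pro_base - mean(mat_pro_base)) / stats::sd(mat_pro_base)
  if (is.null(bias_pattern)) bias_pattern <- matrix(1, nlat, nlon)
  if (!all(dim(bias_pattern) == c(nlat, nlon)))
    stop("bias_pattern not conformable with the model grid")
  members <- lapply(seq_len(coupling$n_models), function(i) {
    bias_field <- coupling$bias[i] * bias_pattern +
      coupling$bias_field_sd * gaussian_field(nlat, nlon, 5)
    loss_his <- matrix(pmax(0.05, truth$values + bias_field), nlat, nlon)
    gl <- coupling_link(coupling, loss_his)
    eps <- function() matrix(stats::rnorm(nlat * nlon, 0,
                                          coupling$noise_sd), nlat, nlon)
    npp <- coupling$alpha_npp[i] + coupling$beta_npp[i] * gl +
      coupling$climate_effect * zmat + eps()
    hr <- coupling$alpha_hr[i] + coupling$beta_hr[i] * gl +
      0.6 * coupling$climate_effect * zmat + eps()
    fg <- function(v, un, nm, per) flux_grid(v, truth$lat, truth$lon,
                                             units = un, variable = nm,
                                             period = per)
    structure(list(
      name = sprintf("model_%02d", i),
      loss_his = fg(loss_his, "Mg ha-1 yr-1", "LOSS", c(1961L, 2014L)),
      npp_pro = fg(npp, "gC m-2 yr-1", "NPP", c(2015L, 2099L)),
      hr_pro = fg(hr, "gC m-2 yr-1", "HR", c(2015L, 2099L)),
      mat_pro = fg(mat_pro_base, "degC", "MAT", c(2015L, 2099L)),
      map_pro = fg(map_pro_base, "mm yr-1", "MAP", c(2015L, 2099L)),
      mean_bias = coupling$bias[i]), class = "model_fields")
  })
  structure(list(members = members, mask = mask, truth = truth,
                 coupling = coupling, resolution = model_resolution,
                 seed = seed),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d members at %.2f deg, %d forest cells\n",
              length(x$members), x$resolution, sum(x$mask)))
  invisible(x)
}
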