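#' Compare ensemble historical LOSS with the observed LOSS map
#'
#' Cellwise ensemble statistics of the members' historical LOSS — mean,
#' across-model coefficient of variation (CV, % = 100 sd / mean, undefined
#' where the mean is 0) — and the model-minus-observation difference map
#' `delta = ensemble mean - observed`.
#'
#' @param ensemble a `model_ensemble` or list of `model_fields` (at least 2
#'   members for a CV).
#' @param obs observed LOSS `flux_grid`, already on the model grid.
#' @return list of `flux_grid`s: `delta`, `ens_mean`, `ens_cv`.
#' @export
compare_model_obs <- function(ensemble, obs) {
  members <- if (inherits(ensemble, "model_ensemble")) ensemble$members
             else ensemble
  if (length(members) < 2) stop("need at least 2 models for an ensemble CV")
  g0 <- members[[1]]$loss_his
  stopifnot(inherits(obs, "flux_grid"))
  if (!all(dim(obs$values) == dim(g0$values)))
    stop("observation grid not co-registered with the model grid")
  arr <- simplify2array(lapply(members, function(m) m$loss_his$values))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  cv <- ifelse(is.na(mu) | mu == 0, NA_real_, 100 * sdv / mu)
  fg <- function(v, un, nm) flux_grid(v, g0$lat, g0$lon, units = un,
                                      variable = nm)
  list(delta = fg(mu - obs$values, g0$units, "dLOSS"),
       ens_mean = fg(mu, g0$units, "LOSS_ens_mean"),
       ens_cv = fg(cv, "%", "LOSS_ens_CV"))
}

#' Train a per-model surrogate from historical LOSS to a projected flux
#'
#' Random-forest regression (1000 trees, maximum depth 10) that emulates
#' one ensemble member's mapping from its own historical LOSS — without
#' (`"noclim"`) or with (`"clim"`) projected mean annual temperature and
#' precipitation as extra predictors — to its projected NPP or HR at grid
#' scale. Trained on a random 80% of the member's forest cells and
#' validated on the held-out 20%; the validation correlation is recorded,
#' never used to refuse a fit.
#'
#' @param model a `model_fields` object.
#' @param flux `"npp"` or `"hr"`.
#' @param scenario `"noclim"` (LOSS only) or `"clim"` (LOSS + MAT + MAP).
#' @param mask logical matrix of forest cells; at least 100 complete cells
#'   are required.
#' @param split_seed integer seed for the 80/20 split and the forest.
#' @param num_trees,max_depth surrogate hyperparameters.
#' @return object of class `surrogate` with the fitted regressor, the
#'   split bookkeeping, validation correlation `validation_r` and RMSE.
#' @export
train_surrogate <- function(model, flux = c("npp", "hr"),
                            scenario = c("noclim", "clim"), mask,
                            split_seed = 1, num_trees = 1000,
                            max_depth = 10) {
  flux <- match.arg(flux)
  if (!scenario[1] %in% c("noclim", "clim"))
    stop("unknown scenario: ", scenario[1])
  scenario <- scenario[1]
  y_grid <- if (flux == "npp") model$npp_pro else model$hr_pro
  preds <- list(loss_his = model$loss_his$values)
  if (scenario == "clim") {
    preds$mat_pro <- model$mat_pro$values
    preds$map_pro <- model$map_pro$values
  }
  idx <- which(mask & !is.na(y_grid$values) &
                 Reduce(`&`, lapply(preds, function(m) !is.na(m))))
  if (length(idx) < 100)
    stop("need at least 100 complete forest cells, got ", length(idx))
  df <- as.data.frame(lapply(preds, function(m) m[idx]))
  df$.y <- y_grid$values[idx]
  set.seed(split_seed)
  n <- nrow(df)
  train <- sample.int(n, floor(0.8 * n))
  fit <- ranger::ranger(stats::reformulate(names(preds), ".y"),
                        data = df[train, ], num.trees = num_trees,
                        max.depth = max_depth, seed = split_seed)
  hold <- setdiff(seq_len(n), train)
  pv <- stats::predict(fit, df[hold, names(preds), drop = FALSE])$predictions
  structure(list(model_name = model$name, flux = flux, scenario = scenario,
                 regressor = fit, predictors = names(preds),
                 cells = idx, train = idx[train], holdout = idx[hold],
                 validation_r = stats::cor(pv, df$.y[hold]),
                 validation_rmse = sqrt(mean((pv - df$.y[hold])^2)),
                 units = y_grid$units, split_seed = split_seed),
            class = "surrogate")
}

#' @export
print.surrogate <- function(x, ...) {
  cat(sprintf(paste0("<surrogate> %s %s (%s): validation R = %.3f, ",
                     "RMSE = %.3g %s\n"), x$model_name, toupper(x$flux),
              x$scenario, x$validation_r, x$validation_rmse, x$units))
  invisible(x)
}

# predict a flux grid from a surrogate given a LOSS matrix (and the
# member's own projected climate when the scenario demands it)
predict_surrogate <- function(surrogate, loss_values, model, mask) {
  idx <- which(mask & !is.na(loss_values))
  nd <- data.frame(loss_his = loss_values[idx])
  if (surrogate$scenario == "clim") {
    nd$mat_pro <- model$mat_pro$values[idx]
    nd$map_pro <- model$map_pro$values[idx]
  }
  out <- matrix(NA_real_, nrow(loss_values), ncol(loss_values))
  out[idx] <- stats::predict(surrogate$regressor, nd)$predictions
  out
}

#' Build the bootstrap observational LOSS constraint
#'
#' Combines the two upscaling bootstrap ensembles into the overall
#' observational product: the overall mean map is the average of the two
#' ensemble means, and the overall standard-deviation map is twice the sum
#' of the two per-scheme standard deviations (`sd_j = mean_j * CV_j / 100`)
#' — a deliberately conservative inflation absorbing uncertainty sources
#' (e.g. the covariates themselves) that the bootstraps cannot see. An
#' alternative quadrature combination `2 * sqrt(sd_1^2 + sd_2^2)` is
#' available via `combine = "quadrature"`. From the overall mean and sd,
#' `n_maps` observation maps are drawn as independent per-cell Gaussians
#' truncated at zero (LOSS is physically non-negative).
#'
#' @param ens1,ens2 `bootstrap_ensemble`s (e.g. stratified and random
#'   schemes), co-registered.
#' @param n_maps number of sampled mean maps (default 100).
#' @param seed integer RNG seed.
#' @param combine `"sum"` (default) or `"quadrature"`.
#' @return object of class `loss_observation`: `mean` and `sd` matrices,
#'   `maps` (list of `n_maps` matrices), `grid` template, `seed`.
#' @export
build_loss_observation <- function(ens1, ens2, n_maps = 100, seed = 1,
                                   combine = c("sum", "quadrature")) {
  stopifnot(inherits(ens1, "bootstrap_ensemble"),
            inherits(ens2, "bootstrap_ensemble"))
  combine <- match.arg(combine)
  if (!all(dim(ens1$mean) == dim(ens2$mean)))
    stop("bootstrap ensembles are not co-registered")
  if (any(ens1$cv < 0, na.rm = TRUE) || any(ens2$cv < 0, na.rm = TRUE))
    stop("negative CV input")
  mu <- (ens1$mean + ens2$mean) / 2
  sd1 <- ens1$mean * ens1$cv / 100
  sd2 <- ens2$mean * ens2$cv / 100
  sdv <- if (combine == "sum") 2 * (sd1 + sd2)
         else 2 * sqrt(sd1^2 + sd2^2)
  set.seed(seed)
  maps <- lapply(seq_len(n_maps), function(b) {
    m <- mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) * sdv
    m[!is.na(m) & m < 0] <- 0
    m
  })
  structure(list(mean = mu, sd = sdv, maps = maps,
                 grid = ens1$mean_grid, n_maps = n_maps, seed = seed,
                 combine = combine),
            class = "loss_observation")
}

#' @export
print.loss_observation <- function(x, ...) {
  cat(sprintf(paste0("<loss_observation> %d sampled maps; overall mean ",
                     "%.2f, overall sd %.2f (cell medians)\n"), x$n_maps,
              stats::median(x$mean, na.rm = TRUE),
              stats::median(x$sd, na.rm = TRUE)))
  invisible(x)
}

#' Construct a LossObservation directly from a mean and sd map
#'
#' Lower-level constructor used when the overall mean/sd maps come from
#' elsewhere (e.g. a deposited product) rather than from two in-session
#' bootstrap ensembles.
#'
#' @param mean_map,sd_map matrices (or `flux_grid`s) of the overall mean
#'   and overall standard deviation of LOSS.
#' @param grid template `flux_grid`.
#' @inheritParams build_loss_observation
#' @return a `loss_observation`.
#' @export
loss_observation_from_maps <- function(mean_map, sd_map, grid,
                                       n_maps = 100, seed = 1) {
  mu <- if (inherits(mean_map, "flux_grid")) mean_map$values else mean_map
  sdv <- if (inherits(sd_map, "flux_grid")) sd_map$values else sd_map
  if (any(sdv < 0, na.rm = TRUE)) stop("sd map must be >= 0")
  set.seed(seed)
  maps <- lapply(seq_len(n_maps), function(b) {
    m <- mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) * sdv
    m[!is.na(m) & m < 0] <- 0
    m
  })
  structure(list(mean = mu, sd = sdv, maps = maps, grid = grid,
                 n_maps = n_maps, seed = seed, combine = "direct"),
            class = "loss_observation")
}

#' Apply the machine-learning observational constraint
#'
#' For every ensemble member and every sampled observation map, feeds the
#' observed LOSS into the member's trained surrogate, predicts the
#' constrained projected flux grid, and aggregates it to continental sums
#' (Pg C yr-1). Returns before- and after-constraint continental values per
#' model, the across-model mean/min/max convention used for reporting, and
#' the net sink `NEE = NPP - HR` per continent, which holds as an exact
#' identity in the aggregates.
#'
#' @param surrogates list of `surrogate`s covering every member for each
#'   flux in `fluxes` (same scenario throughout).
#' @param ensemble the `model_ensemble` the surrogates were trained on.
#' @param obs a `loss_observation` on the model grid.
#' @param regions a `region_set`.
#' @param mask logical forest-cell matrix; defaults to the ensemble mask.
#' @param fluxes which fluxes to constrain (default both).
#' @param loss_unit_scale multiplier standardizing the observation maps to
#'   the ensemble's LOSS units before feeding (1 when both are biomass
#'   Mg ha-1 yr-1, as in the synthetic ensemble).
#' @param carbon_fraction passed to [aggregate_regional()].
#' @return object of class `constraint_result`: `before` (model x region x
#'   flux array of unconstrained sums, NEE included), `after` (model x
#'   map x region x flux array), `summary` data.frame (per region and flux:
#'   before/after across-model mean, sd, min, max), and bookkeeping.
#' @export
apply_constraint <- function(surrogates, ensemble, obs, regions,
                             mask = NULL, fluxes = c("npp", "hr"),
                             loss_unit_scale = 1, carbon_fraction = 0.5) {
  stopifnot(inherits(obs, "loss_observation"),
            inherits(regions, "region_set"))
  members <- ensemble$members
  if (is.null(mask)) mask <- ensemble$mask
  g0 <- members[[1]]$loss_his
  if (!all(dim(obs$mean) == dim(g0$values)))
    stop("observation maps not on the model grid")
  areas <- cell_areas(g0)
  model_names <- vapply(members, `[[`, "", "name")
  sur_key <- vapply(surrogates, function(s)
    paste(s$model_name, s$flux, sep = "."), "")
  names(surrogates) <- sur_key
  for (m in model_names) for (fx in fluxes)
    if (!paste(m, fx, sep = ".") %in% sur_key)
      stop("missing surrogate for ", m, " ", toupper(fx))
  region_names <- regions$regions
  regsum <- function(values, units) {
    g <- flux_grid(values, g0$lat, g0$lon, units = units)
    agg <- aggregate_regional(g, areas, mask, regions, carbon_fraction)
    stats::setNames(agg$total_PgC, agg$region)[region_names]
  }
  M <- length(members); B <- obs$n_maps
  out_fluxes <- c(fluxes, "nee")
  before <- array(NA_real_, c(M, length(region_names), length(out_fluxes)),
                  dimnames = list(model_names, region_names, out_fluxes))
  after <- array(NA_real_,
                 c(M, B, length(region_names), length(out_fluxes)),
                 dimnames = list(model_names, NULL, region_names,
                                 out_fluxes))
  for (i in seq_len(M)) {
    mdl <- members[[i]]
    for (fx in fluxes) {
      fx_grid <- if (fx == "npp") mdl$npp_pro else mdl$hr_pro
      before[i, , fx] <- regsum(fx_grid$values, fx_grid$units)
      sur <- surrogates[[paste(mdl$name, fx, sep = ".")]]
      for (b in seq_len(B)) {
        pred <- predict_surrogate(sur, obs$maps[[b]] * loss_unit_scale,
                                  mdl, mask)
        after[i, b, , fx] <- regsum(pred, sur$units)
      }
    }
  }
  if (all(c("npp", "hr") %in% fluxes)) {
    before[, , "nee"] <- before[, , "npp"] - before[, , "hr"]
    after[, , , "nee"] <- after[, , , "npp"] - after[, , , "hr"]
  }
  # per-model after value = mean over the bootstrap observation maps
  after_model <- apply(after, c(1, 3, 4), mean)
  rows <- expand.grid(region = region_names, flux = out_fluxes,
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    rg <- rows$region[r]; fx <- rows$flux[r]
    bf <- before[, rg, fx]; af <- after_model[, rg, fx]
    data.frame(region = rg, flux = toupper(fx),
               before_mean = mean(bf), before_sd = stats::sd(bf),
               before_min = min(bf), before_max = max(bf),
               after_mean = mean(af), after_sd = stats::sd(af),
               after_min = min(af), after_max = max(af))
  }))
  structure(list(before = before, after = after,
                 after_model = after_model, summary = summ,
                 regions = region_names, fluxes = out_fluxes,
                 n_maps = B, scenario = surrogates[[1]]$scenario),
            class = "constraint_result")
}

#' @export
print.constraint_result <- function(x, ...) {
  cat(sprintf(paste0("<constraint_result> %d models x %d observation maps",
                     ", scenario '%s'\n"), dim(x$before)[1], x$n_maps,
              x$scenario))
  s <- x$summary
  s[, -(1:2)] <- round(s[, -(1:2)], 2)
  print.data.frame(s[, c("region", "flux", "before_mean", "before_sd",
                         "after_mean", "after_sd")], row.names = FALSE)
  invisible(x)
}

#' Test the before/after-constraint difference per continent and flux
#'
#' One-way ANOVA between unconstrained and constrained continental values.
#' `pooling = "model"` (default) compares M model-level values before vs M
#' model-level map-means after; `pooling = "pooled"` uses every model x
#' bootstrap-map value in the after group, which inflates the sample size —
#' significance under pooling should be read with that caveat. Also
#' reports the spread (across-model sd) before and after.
#'
#' @param result a `constraint_result`, or a numeric vector of
#'   before-constraint values (then `after` must be the matching
#'   after-constraint vector and a single test is returned).
#' @param after optional numeric vector of after-constraint values.
#' @param pooling `"model"` or `"pooled"`.
#' @return data.frame (class `before_after_test`): per region and flux,
#'   `F`, `p`, `stars`, `sd_before`, `sd_after`, group sizes.
#' @export
compare_before_after <- function(result, after = NULL,
                                 pooling = c("model", "pooled")) {
  pooling <- match.arg(pooling)
  if (is.numeric(result)) {
    if (!is.numeric(after)) stop("need an 'after' vector")
    if (length(result) < 2 || length(after) < 2)
      stop("degenerate groups: need >= 2 values per group")
    stat <- anova_oneway(result, after)
    return(structure(
      data.frame(F = stat$F, p = stat$p, stars = p_stars(stat$p),
                 sd_before = stats::sd(result), sd_after = stats::sd(after),
                 n_before = length(result), n_after = length(after)),
      pooling = pooling, class = c("before_after_test", "data.frame")))
  }
  stopifnot(inherits(result, "constraint_result"))
  rows <- expand.grid(region = result$regions, flux = result$fluxes,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    rg <- rows$region[r]; fx <- rows$flux[r]
    bf <- result$before[, rg, fx]
    af <- if (pooling == "model") result$after_model[, rg, fx]
          else as.vector(result$after[, , rg, fx])
    if (length(bf) < 2 || length(af) < 2)
      stop("degenerate groups for ", rg, " ", fx)
    stat <- anova_oneway(bf, af)
    data.frame(region = rg, flux = toupper(fx), F = stat$F, p = stat$p,
               stars = p_stars(stat$p), sd_before = stats::sd(bf),
               sd_after = stats::sd(result$after_model[, rg, fx]),
               n_before = length(bf), n_after = length(af))
  }))
  rownames(out) <- NULL
  structure(out, pooling = pooling,
            class = c("before_after_test", "data.frame"))
}

# one-way ANOVA on two groups via stats::aov; F = 0, p = 1 for identical
# groups with zero residual variance
anova_oneway <- function(g1, g2) {
  d <- data.frame(y = c(g1, g2),
                  g = factor(rep(c("before", "after"),
                                 c(length(g1), length(g2)))))
  tab <- stats::anova(stats::aov(y ~ g, data = d))
  f <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  if (!is.finite(f)) { f <- 0; p <- 1 }   # zero between & within variance
  list(F = f, p = p)
}
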