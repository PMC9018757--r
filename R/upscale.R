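#' Build the covariate table for upscaling
#'
#' One row per observation cell: the gridded LOSS response, the world's
#' covariate values at the cell, and the biome label (used by the
#' stratified bootstrap). Convenience bridge between the synthetic world /
#' gridded observations and the model-fitting functions; a real application
#' would assemble the same layout from its own covariate rasters.
#'
#' @param world a `synthetic_world`.
#' @param obs result of [aggregate_to_grid()] (or any `flux_grid` on the
#'   world grid, passed as `obs$loss`).
#' @return data.frame with columns `loss`, `biome`, `cell` (linear cell
#'   index) and one column per covariate.
#' @export
covariate_table <- function(world, obs) {
  stopifnot(inherits(world, "synthetic_world"))
  g <- if (inherits(obs, "flux_grid")) obs else obs$loss
  if (!all(dim(g$values) == dim(world$loss_true)))
    stop("observation grid not co-registered with the world")
  idx <- which(!is.na(g$values))
  df <- data.frame(loss = g$values[idx], biome = world$biome[idx],
                   cell = idx, stringsAsFactors = FALSE)
  for (nm in names(world$covariates)) df[[nm]] <- world$covariates[[nm]][idx]
  df
}

#' Drop collinear covariates by pairwise correlation and VIF
#'
#' Two-stage filter: (i) while any covariate pair has `|r| > r_max`, drop
#' the member of the worst pair with the larger mean absolute correlation
#' to the remaining covariates (deterministic tie-break: first column
#' order); (ii) while any variance-inflation factor is `>= vif_max`, drop
#' the covariate with the largest VIF. Zero-variance covariates are removed
#' up front.
#'
#' @param table data.frame; all columns except `exclude` are candidate
#'   covariates.
#' @param r_max pairwise correlation threshold (default 0.7; survivors have
#'   `|r| <= r_max`).
#' @param vif_max VIF threshold (default 4; survivors have `VIF < vif_max`).
#' @param exclude column names to pass through untouched (e.g. the
#'   response, ids, biome labels).
#' @return list with `table` (reduced data.frame, excluded columns first)
#'   and `log` (data.frame of removals: `variable`, `reason`, `value`).
#' @export
filter_collinear <- function(table, r_max = 0.7, vif_max = 4,
                             exclude = c("loss", "biome", "cell",
                                         "plot_id")) {
  keep_cols <- intersect(exclude, names(table))
  cand <- setdiff(names(table), keep_cols)
  cand <- cand[vapply(table[cand], is.numeric, TRUE)]
  if (length(cand) < 2) stop("need at least two numeric covariates")
  log <- data.frame(variable = character(0), reason = character(0),
                    value = numeric(0))
  note <- function(v, why, val)
    log <<- rbind(log, data.frame(variable = v, reason = why, value = val))
  sds <- vapply(table[cand], stats::sd, 0)
  for (v in cand[sds == 0]) note(v, "zero variance", 0)
  cand <- cand[sds > 0]
  repeat {
    if (length(cand) < 2) break
    cm <- abs(stats::cor(table[cand]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- cand[worst]
    mean_abs <- colMeans(cm[, pair, drop = FALSE])
    drop <- pair[which.max(mean_abs)]
    note(drop, sprintf("pairwise |r| > %.2f with %s", r_max,
                       setdiff(pair, drop)), max(cm))
    cand <- setdiff(cand, drop)
  }
  repeat {
    if (length(cand) < 2) break
    vifs <- vif_values(table[cand])
    if (max(vifs) < vif_max) break
    drop <- cand[which.max(vifs)]
    note(drop, sprintf("VIF >= %.1f", vif_max), max(vifs))
    cand <- setdiff(cand, drop)
  }
  list(table = table[c(keep_cols, cand)], log = log)
}

# VIF_j = 1 / (1 - R^2 of covariate j regressed on the others)
vif_values <- function(df) {
  r <- stats::cor(df)
  v <- diag(solve(r))
  names(v) <- names(df)
  v
}

#' Fit the plot-to-map random-forest upscaler with k-fold cross-validation
#'
#' Random forest regression of gridded plot LOSS on environmental
#' covariates, evaluated with k-fold cross-validation (out-of-fold R-squared
#' pooled over folds, plus its spread across folds) and then refit on all
#' rows for mapping.
#'
#' @param table covariate table with a `loss` response column (typically the
#'   output of [filter_collinear()]).
#' @param k number of folds (default 10). Requires `nrow(table) > k`.
#' @param seed integer seed controlling fold assignment and the forest.
#' @param num_trees,mtry,max_depth forest hyperparameters; defaults are 500
#'   trees, `sqrt(p)` candidate splits and unlimited depth.
#' @param response name of the response column.
#' @return object of class `loss_upscaler`: the refit `ranger` model,
#'   `cv` (pooled out-of-fold `r2`, per-fold `fold_r2`, `sd`), the final
#'   in-sample fit `r2_fit`, covariate names and fold assignment.
#' @export
fit_upscaler <- function(table, k = 10, seed = 1, num_trees = 500,
                         mtry = NULL, max_depth = NULL,
                         response = "loss") {
  if (!response %in% names(table)) stop("no response column '", response, "'")
  covs <- setdiff(names(table),
                  c(response, "biome", "cell", "plot_id"))
  covs <- covs[vapply(table[covs], is.numeric, TRUE)]
  n <- nrow(table)
  if (n <= k) stop("need more rows than folds (n = ", n, ", k = ", k, ")")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(length(covs))))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  y <- table[[response]]
  pred <- rep(NA_real_, n)
  fold_r2 <- numeric(k)
  fml <- stats::reformulate(covs, response)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- ranger::ranger(fml, data = table[tr, c(response, covs)],
                          num.trees = num_trees, mtry = mtry,
                          max.depth = max_depth, seed = seed + f)
    p <- stats::predict(fit, table[!tr, covs, drop = FALSE])$predictions
    pred[!tr] <- p
    fold_r2[f] <- 1 - sum((y[!tr] - p)^2) / sum((y[!tr] - mean(y[!tr]))^2)
  }
  cv_r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  final <- ranger::ranger(fml, data = table[, c(response, covs)],
                          num.trees = num_trees, mtry = mtry,
                          max.depth = max_depth, seed = seed)
  fit_pred <- stats::predict(final, table[, covs, drop = FALSE])$predictions
  structure(list(model = final, covariates = covs, response = response,
                 cv = list(r2 = cv_r2, fold_r2 = fold_r2,
                           sd = stats::sd(fold_r2)),
                 r2_fit = 1 - sum((y - fit_pred)^2) /
                   sum((y - mean(y))^2),
                 folds = folds, seed = seed,
                 hyper = list(num_trees = num_trees, mtry = mtry,
                              max_depth = max_depth)),
            class = "loss_upscaler")
}

#' @export
print.loss_upscaler <- function(x, ...) {
  cat(sprintf(paste0("<loss_upscaler> %d covariates, %d trees; CV R2 = ",
                     "%.3f (fold sd %.3f), fit R2 = %.3f\n"),
              length(x$covariates), x$hyper$num_trees, x$cv$r2, x$cv$sd,
              x$r2_fit))
  invisible(x)
}

#' @export
predict.loss_upscaler <- function(object, newdata, ...) {
  stats::predict(object$model,
                 newdata[, object$covariates, drop = FALSE])$predictions
}

#' Predict a LOSS map from a fitted upscaler
#'
#' @param model a `loss_upscaler`.
#' @param stack named list of covariate matrices covering the grid; must
#'   include every training covariate.
#' @param mask logical matrix of cells to predict (e.g. a forest mask).
#' @param grid template `flux_grid` giving coordinates.
#' @return a `flux_grid` of predicted LOSS (Mg ha-1 yr-1), missing outside
#'   the mask.
#' @export
predict_map <- function(model, stack, mask, grid) {
  stopifnot(inherits(model, "loss_upscaler"), inherits(grid, "flux_grid"))
  miss <- setdiff(model$covariates, names(stack))
  if (length(miss))
    stop("missing covariate layer(s): ", paste(miss, collapse = ", "))
  out <- matrix(NA_real_, length(grid$lat), length(grid$lon))
  idx <- which(mask)
  if (length(idx)) {
    nd <- as.data.frame(lapply(stack[model$covariates],
                               function(m) m[idx]))
    names(nd) <- model$covariates
    out[idx] <- predict(model, nd)
  }
  flux_grid(out, grid$lat, grid$lon, units = "Mg ha-1 yr-1",
            variable = "LOSS")
}

#' Bootstrap map ensembles and their cellwise uncertainty
#'
#' Refits the upscaler on resampled covariate tables and maps each refit,
#' yielding an ensemble of LOSS maps with a cellwise mean, coefficient of
#' variation (CV, % = 100 sd / mean) and 95% interval. Two schemes:
#' `"stratified"` (default 100 iterations) resamples with replacement
#' within biome strata, preserving every stratum's sample count;
#' `"random"` (default 10 iterations) draws 90% of rows with replacement.
#'
#' @param table covariate table (needs `biome` for the stratified scheme).
#' @param stack,mask,grid as in [predict_map()].
#' @param scheme `"stratified"` or `"random"`.
#' @param iterations number of bootstrap members; `NULL` uses the scheme
#'   default (100 stratified / 10 random).
#' @param seed integer RNG seed.
#' @param num_trees trees per member forest.
#' @return object of class `bootstrap_ensemble`: `members` (list of value
#'   matrices), `mean`/`cv`/`q025`/`q975` matrices, `mean_grid` and
#'   `cv_grid` as `flux_grid`s, plus scheme bookkeeping.
#' @export
bootstrap_maps <- function(table, stack, mask, grid,
                           scheme = c("stratified", "random"),
                           iterations = NULL, seed = 1, num_trees = 250) {
  scheme <- match.arg(scheme)
  if (is.null(iterations))
    iterations <- if (scheme == "stratified") 100L else 10L
  if (scheme == "stratified" && !"biome" %in% names(table))
    stop("stratified scheme needs biome labels")
  covs <- setdiff(names(table), c("loss", "biome", "cell", "plot_id"))
  covs <- covs[vapply(table[covs], is.numeric, TRUE)]
  fml <- stats::reformulate(covs, "loss")
  set.seed(seed)
  n <- nrow(table)
  idx_fun <- if (scheme == "stratified") {
    strata <- split(seq_len(n), table$biome)
    function() unlist(lapply(strata, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]),
      use.names = FALSE)
  } else {
    n_draw <- round(0.9 * n)
    function() sample.int(n, n_draw, replace = TRUE)
  }
  cells <- which(mask)
  nd <- as.data.frame(lapply(stack[covs], function(mm) mm[cells]))
  names(nd) <- covs
  members <- vector("list", iterations)
  draws <- vector("list", iterations)
  for (b in seq_len(iterations)) {
    idx <- idx_fun()
    draws[[b]] <- idx
    fit <- ranger::ranger(fml, data = table[idx, c("loss", covs)],
                          num.trees = num_trees,
                          mtry = max(1, floor(sqrt(length(covs)))),
                          seed = seed + b)
    pm <- matrix(NA_real_, length(grid$lat), length(grid$lon))
    pm[cells] <- stats::predict(fit, nd)$predictions
    members[[b]] <- pm
  }
  arr <- simplify2array(members)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  cv <- ifelse(is.na(mu) | mu == 0, NA_real_, 100 * sdv / mu)
  qfun <- function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  q <- apply(arr, c(1, 2), qfun)
  as_grid <- function(v, un, nm)
    flux_grid(v, grid$lat, grid$lon, units = un, variable = nm)
  structure(list(members = members, mean = mu, cv = cv,
                 q025 = q[1, , ], q975 = q[2, , ],
                 mean_grid = as_grid(mu, "Mg ha-1 yr-1", "LOSS"),
                 cv_grid = as_grid(cv, "%", "LOSS_CV"),
                 scheme = scheme, iterations = iterations, seed = seed,
                 draws = draws),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_ensemble> %s scheme, %d members; ",
                     "median CV %.1f%%\n"), x$scheme, x$iterations,
              stats::median(x$cv, na.rm = TRUE)))
  invisible(x)
}

#' Permutation importance (%IncMSE) of upscaler covariates
#'
#' For each covariate, permutes that column, re-predicts, and reports the
#' percentage increase in mean squared error relative to the unpermuted
#' predictions, averaged over `repeats` permutations. Larger %IncMSE means
#' a more important covariate; permuting nothing gives 0 by construction.
#'
#' @param model a `loss_upscaler`.
#' @param table the table it was trained on (or comparable held-out data).
#' @param repeats permutations per covariate (default 10).
#' @param seed integer RNG seed.
#' @return data.frame (class `importance_table`) with `covariate`,
#'   `inc_mse` (%) and `rank` (1 = most important), sorted by rank.
#' @export
variable_importance <- function(model, table, repeats = 10, seed = 1) {
  stopifnot(inherits(model, "loss_upscaler"))
  set.seed(seed)
  y <- table[[model$response]]
  base_mse <- mean((y - predict(model, table))^2)
  inc <- vapply(model$covariates, function(v) {
    mses <- vapply(seq_len(repeats), function(r) {
      tp <- table
      tp[[v]] <- sample(tp[[v]])
      mean((y - predict(model, tp))^2)
    }, 0)
    100 * (mean(mses) - base_mse) / base_mse
  }, 0)
  out <- data.frame(covariate = model$covariates, inc_mse = inc)
  out <- out[order(-out$inc_mse), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

#' Standardized driver coefficients from a linear mixed model
#'
#' Regresses LOSS on standardized (z-scored) predictors with a random
#' intercept per grouping unit (each plot as a random effect when
#' census-level rows are supplied), reporting fixed-effect coefficients per
#' one standard deviation of each predictor, with Wald 95% confidence
#' intervals and significance stars. With a degenerate
#' grouping factor (a single level, or one level per row) the model is not
#' identifiable and the function falls back to ordinary least squares with
#' a warning.
#'
#' @param data data.frame of (census- or plot-level) rows.
#' @param response response column name.
#' @param predictors character vector of numeric predictor columns.
#' @param group grouping column name (e.g. `"plot_id"`).
#' @return data.frame (class `driver_fit`) with `term`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p`, `stars`, and a `"method"` attribute
#'   (`"lmm"` or `"ols"`).
#' @export
fit_driver_lmm <- function(data, response, predictors, group) {
  for (v in c(response, predictors, group))
    if (!v %in% names(data)) stop("missing column: ", v)
  d <- data.frame(.y = data[[response]])
  for (v in predictors) d[[v]] <- scale(data[[v]])[, 1]
  d$.g <- factor(data[[group]])
  nlev <- nlevels(d$.g)
  use_lmm <- nlev >= 2 && nlev < nrow(d)
  if (use_lmm) {
    fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = "+"),
                                   "+ (1 | .g)"))
    fit <- lmerTest::lmer(fml, data = d)
    cf <- stats::coef(summary(fit))
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    p <- cf[, "Pr(>|t|)"]
    method <- "lmm"
  } else {
    warning("grouping factor is degenerate (", nlev,
            " level(s) for ", nrow(d), " rows); falling back to OLS")
    fml <- stats::reformulate(predictors, ".y")
    fit <- stats::lm(fml, data = d)
    cf <- stats::coef(summary(fit))
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    p <- cf[, "Pr(>|t|)"]
    method <- "ols"
  }
  keep <- rownames(cf) != "(Intercept)"
  out <- data.frame(term = rownames(cf)[keep], estimate = est[keep],
                    se = se[keep],
                    ci_lower = est[keep] - 1.96 * se[keep],
                    ci_upper = est[keep] + 1.96 * se[keep],
                    p = p[keep], stars = p_stars(p[keep]))
  rownames(out) <- NULL
  structure(out, method = method, model = fit,
            class = c("driver_fit", "data.frame"))
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
}

#' Reineke stand density index
#'
#' Crowding metric combining tree density and quadratic mean diameter:
#' `SDI = N * (Dq / ref_diameter)^exponent`, with Reineke's reference
#' diameter 25.4 cm and exponent 1.605 by default; at `Dq = ref_diameter`
#' the index equals the density, and it is linear in `N`.
#'
#' @param density trees per hectare (`> 0`).
#' @param dq quadratic mean diameter in cm (`> 0`).
#' @param ref_diameter,exponent Reineke constants.
#' @return numeric SDI, vectorized.
#' @export
stand_density_index <- function(density, dq, ref_diameter = 25.4,
                                exponent = 1.605) {
  if (any(density <= 0) || any(dq <= 0))
    stop("density and quadratic mean diameter must be positive")
  density * (dq / ref_diameter)^exponent
}
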