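#' Aggregate ensemble fields and observations for an emergent constraint
#'
#' Produces, for one region, the across-ensemble constraint inputs: each
#' member's historical LOSS aggregate `x_i` (averaged at plot locations in
#' `"plot-sites"` mode, or area-weighted over the region's forest cells in
#' `"continental-map"` mode), its projected flux regional sum `y_i`
#' (Pg C yr-1), and the matching observational mean and spread.
#'
#' In plot-sites mode the observational spread defaults to the standard
#' error of the plot mean (`sigma = "se"`); set `sigma = "sd"` for the plot
#' standard deviation. In continental-map mode the observation comes from a
#' LOSS map (`obs_map`) and its bootstrap CV map when available.
#'
#' @param ensemble a `model_ensemble` (or list of `model_fields`).
#' @param flux which projected flux to aggregate: `"npp"` or `"hr"`.
#' @param regions a `region_set`; `region` names the region to use.
#' @param region region name.
#' @param mode `"plot-sites"` or `"continental-map"`.
#' @param plots plot table (plot-sites mode).
#' @param obs_map observed LOSS `flux_grid` on the model grid
#'   (continental-map mode).
#' @param obs_cv optional CV (%) matrix matching `obs_map`, used for
#'   `sigma_obs` in continental-map mode.
#' @param mask logical matrix of forest cells on the model grid; defaults
#'   to the ensemble's own mask.
#' @param sigma `"se"` or `"sd"` (plot-sites mode).
#' @param carbon_fraction passed to [aggregate_regional()].
#' @return list with `x`, `y` (named per model), `mu_obs`, `sigma_obs`,
#'   `region`, `mode`, `flux`.
#' @export
aggregate_for_ec <- function(ensemble, flux = c("npp", "hr"), regions,
                             region, mode = c("plot-sites",
                                              "continental-map"),
                             plots = NULL, obs_map = NULL, obs_cv = NULL,
                             mask = NULL, sigma = c("se", "sd"),
                             carbon_fraction = 0.5) {
  flux <- match.arg(flux); mode <- match.arg(mode)
  sigma <- match.arg(sigma)
  members <- if (inherits(ensemble, "model_ensemble")) ensemble$members
             else ensemble
  if (is.null(mask) && inherits(ensemble, "model_ensemble"))
    mask <- ensemble$mask
  g0 <- members[[1]]$loss_his
  if (is.null(mask)) mask <- matrix(TRUE, length(g0$lat), length(g0$lon))
  areas <- cell_areas(g0)
  member_region <- region_membership(regions, g0)
  in_region <- mask & !is.na(member_region) & member_region == region
  fx_name <- if (flux == "npp") "npp_pro" else "hr_pro"
  y <- vapply(members, function(m) {
    agg <- aggregate_regional(m[[fx_name]], areas, mask, regions,
                              carbon_fraction)
    agg$total_PgC[agg$region == region]
  }, 0)
  if (mode == "plot-sites") {
    if (is.null(plots)) stop("plot-sites mode needs a plot table")
    pm <- region_membership(regions, lon = plots$lon, lat = plots$lat)
    p <- plots[!is.na(pm) & pm == region, , drop = FALSE]
    if (nrow(p) == 0) stop("no plots in region '", region, "'")
    ij <- cell_index(g0, p$lon, p$lat)
    x <- vapply(members, function(m) mean(m$loss_his$values[ij]), 0)
    mu_obs <- mean(p$loss)
    sigma_obs <- if (sigma == "se") stats::sd(p$loss) / sqrt(nrow(p))
                 else stats::sd(p$loss)
  } else {
    if (is.null(obs_map)) stop("continental-map mode needs obs_map")
    if (!any(in_region)) stop("no forest cells in region '", region, "'")
    wmean <- function(v) {
      ok <- in_region & !is.na(v)
      sum(v[ok] * areas[ok]) / sum(areas[ok])
    }
    x <- vapply(members, function(m) wmean(m$loss_his$values), 0)
    mu_obs <- wmean(obs_map$values)
    sigma_obs <- if (is.null(obs_cv)) 0
                 else wmean(obs_map$values * obs_cv / 100)
  }
  names(x) <- names(y) <- vapply(members, `[[`, "", "name")
  list(x = x, y = y, mu_obs = mu_obs, sigma_obs = sigma_obs,
       region = region, mode = mode, flux = flux)
}

#' Fit the across-ensemble emergent-constraint regression
#'
#' Ordinary least squares of each member's projected regional flux on its
#' historical LOSS aggregate, one point per ensemble member:
#' `y_i = a * x_i + b`. Reports the slope's two-sided p-value and the
#' residual standard deviation on `M - 2` degrees of freedom.
#'
#' @param x historical LOSS aggregates, one per member.
#' @param y projected flux aggregates (Pg C yr-1), same length.
#' @return object of class `ec_fit` with `a`, `b`, `r2`, `p`, `s`, `M`,
#'   and the data.
#' @export
fit_ec <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 ensemble members")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in the ensemble aggregates")
  if (stats::sd(x) == 0) stop("zero variance in x; EC is undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 s = sm$sigma, M = length(x), x = x, y = y, lm = fit),
            class = "ec_fit")
}

#' @export
print.ec_fit <- function(x, ...) {
  cat(sprintf(paste0("<ec_fit> M = %d: y = %.4g x + %.4g, R2 = %.3f, ",
                     "p = %.3g, s = %.4g\n"),
              x$M, x$a, x$b, x$r2, x$p, x$s))
  invisible(x)
}

#' Apply a Gaussian observational constraint to an emergent-constraint fit
#'
#' Standard Gaussian emergent-constraint convolution: the constrained
#' projection is the regression prediction at the observed value, with
#' variance equal to the regression prediction-error variance at the
#' observation plus the slope-scaled observational variance,
#' `var = s^2 (1 + 1/M + (mu - xbar)^2 / Sxx) + a^2 sigma_obs^2`.
#' Equivalently, the mean and variance of `a X + b + e` with
#' `X ~ N(mu_obs, sigma_obs^2)` and `e` the prediction error.
#'
#' When the EC slope is not significant (p > 0.05) the constraint is
#' reported but flagged invalid, with a warning, since a weak across-
#' ensemble relationship cannot carry observational information.
#'
#' @param fit an `ec_fit`.
#' @param mu_obs,sigma_obs observed LOSS mean and spread (same units as the
#'   fit's `x`); `sigma_obs >= 0`.
#' @return object of class `ec_constraint` with `mean`, `sd`, the
#'   unconstrained ensemble `mean_unconstrained`/`sd_unconstrained`,
#'   and `valid` (slope p <= 0.05).
#' @export
constrain_ec <- function(fit, mu_obs, sigma_obs) {
  if (!inherits(fit, "ec_fit")) stop("'fit' must be an ec_fit")
  if (sigma_obs < 0) stop("sigma_obs must be >= 0")
  sxx <- sum((fit$x - mean(fit$x))^2)
  # exact moments of the convolution of the regression predictive
  # distribution with N(mu_obs, sigma_obs^2): the sigma_obs^2 / Sxx term
  # arises because the prediction-error variance itself depends on x
  pred_var <- fit$s^2 * (1 + 1 / fit$M +
                           ((mu_obs - mean(fit$x))^2 + sigma_obs^2) / sxx)
  v <- pred_var + fit$a^2 * sigma_obs^2
  valid <- fit$p <= 0.05
  if (!valid)
    warning(sprintf(paste0("EC slope not significant (p = %.3g); ",
                           "constraint flagged invalid"), fit$p))
  structure(list(mean = fit$a * mu_obs + fit$b, sd = sqrt(v),
                 mean_unconstrained = mean(fit$y),
                 sd_unconstrained = stats::sd(fit$y),
                 mu_obs = mu_obs, sigma_obs = sigma_obs, valid = valid,
                 fit = fit),
            class = "ec_constraint")
}

#' @export
print.ec_constraint <- function(x, ...) {
  cat(sprintf("<ec_constraint> %.4g +/- %.4g (unconstrained %.4g +/- %.4g)%s\n",
              x$mean, x$sd, x$mean_unconstrained, x$sd_unconstrained,
              if (x$valid) "" else " [slope not significant]"))
  invisible(x)
}
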