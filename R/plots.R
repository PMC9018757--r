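#' Screening criteria for forest-plot records
#'
#' Defaults encode the selection used for largely unmanaged, mature,
#' quasi-steady-state plots: (1) at least three censuses and a record
#' spanning more than nine years; (2) unmanaged and undisturbed; (3) mature
#' stands — age above 80 years in boreal and above 100 years in temperate
#' forests, applied only where age is recorded; (4) quasi-steady state —
#' neither growth nor LOSS more than three times the other (zero/zero is
#' excluded too); (5) biomass of at least 3 kg m-2.
#'
#' @param min_censuses,min_span_years criterion 1 thresholds (span is
#'   strict: `span > min_span_years`).
#' @param require_unmanaged criterion 2 switch.
#' @param age_min_boreal,age_min_temperate criterion 3 thresholds (strict).
#' @param ratio_max criterion 4 band half-width: pass iff
#'   `1/ratio_max <= growth/loss <= ratio_max`.
#' @param min_biomass criterion 5 threshold (kg m-2; strictly below fails).
#' @return named list of thresholds.
#' @export
loss_screening_criteria <- function(min_censuses = 3, min_span_years = 9,
                                    require_unmanaged = TRUE,
                                    age_min_boreal = 80,
                                    age_min_temperate = 100,
                                    ratio_max = 3, min_biomass = 3) {
  list(min_censuses = min_censuses, min_span_years = min_span_years,
       require_unmanaged = require_unmanaged,
       age_min_boreal = age_min_boreal,
       age_min_temperate = age_min_temperate,
       ratio_max = ratio_max, min_biomass = min_biomass)
}

#' Screen plot records by the five selection criteria
#'
#' Applies the criteria of [loss_screening_criteria()] in order (1)–(5) and
#' attributes each removed plot to the first criterion it fails, so the
#' filter report reconciles exactly: survivors + per-criterion removals =
#' input count. Screening is idempotent.
#'
#' @param plots data.frame of plot records (see [sample_plots()] for the
#'   column layout). Required: `n_censuses`, `span`, `managed`, `disturbed`,
#'   `loss`, `growth`, `biomass`; `age`/`biome` are used when present.
#' @param criteria list from [loss_screening_criteria()].
#' @return list with `plots` (the survivors) and `report`, a
#'   `filter_report`: data.frame of per-criterion removal counts plus the
#'   per-plot first-failing criterion in its `"first_failure"` attribute.
#' @export
screen_plots <- function(plots, criteria = loss_screening_criteria()) {
  required <- c("n_censuses", "span", "managed", "disturbed", "loss",
                "growth", "biomass")
  for (f in required) {
    if (!f %in% names(plots)) stop("missing mandatory field: ", f)
    if (anyNA(plots[[f]])) {
      bad <- which(is.na(plots[[f]]))[1]
      id <- if ("plot_id" %in% names(plots)) plots$plot_id[bad]
            else as.character(bad)
      stop("plot ", id, ": missing value in mandatory field '", f, "'")
    }
  }
  n <- nrow(plots)
  crit_names <- c("1_record", "2_managed_disturbed", "3_immature",
                  "4_growth_loss_imbalance", "5_low_biomass")
  if (n == 0) {
    rep0 <- data.frame(criterion = crit_names, removed = 0L)
    return(list(plots = plots,
                report = new_filter_report(rep0, 0L, character(0))))
  }
  fail1 <- plots$n_censuses < criteria$min_censuses |
    plots$span <= criteria$min_span_years
  fail2 <- if (criteria$require_unmanaged)
    plots$managed | plots$disturbed else rep(FALSE, n)
  age <- if ("age" %in% names(plots)) plots$age else rep(NA_real_, n)
  biome <- if ("biome" %in% names(plots)) plots$biome else rep(NA, n)
  fail3 <- !is.na(age) &
    ((biome %in% "boreal" & age <= criteria$age_min_boreal) |
     (biome %in% "temperate" & age <= criteria$age_min_temperate))
  g <- plots$growth; l <- plots$loss
  fail4 <- g > criteria$ratio_max * l | l > criteria$ratio_max * g |
    (g == 0 & l == 0)
  fail5 <- plots$biomass < criteria$min_biomass
  fails <- cbind(fail1, fail2, fail3, fail4, fail5)
  first <- apply(fails, 1, function(r) if (any(r)) which(r)[1] else 0L)
  removed <- vapply(1:5, function(k) sum(first == k), 0L)
  survivors <- plots[first == 0L, , drop = FALSE]
  rownames(survivors) <- NULL
  first_chr <- ifelse(first == 0L, "pass", crit_names[pmax(first, 1L)])
  rep_df <- data.frame(criterion = crit_names, removed = removed)
  list(plots = survivors,
       report = new_filter_report(rep_df, nrow(survivors), first_chr))
}

new_filter_report <- function(df, surviving, first_failure) {
  structure(df, surviving = surviving, first_failure = first_failure,
            class = c("filter_report", "data.frame"))
}

#' @export
print.filter_report <- function(x, ...) {
  n_in <- attr(x, "surviving") + sum(x$removed)
  cat(sprintf("Plot screening: %d in, %d removed, %d surviving\n",
              n_in, sum(x$removed), attr(x, "surviving")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Convert aboveground LOSS to total (above- plus belowground) LOSS
#'
#' Applies the root-shoot biomass ratio `r`:
#' `total = aboveground * (1 + r)`, element-wise. Works on a plot table
#' (adding/overwriting the `loss` column from a per-plot ratio) or a
#' `flux_grid` with a co-registered ratio grid.
#'
#' @param x plot data.frame with a `loss` column, or a `flux_grid`.
#' @param root_shoot_ratio numeric vector (per plot) / scalar / matrix
#'   (per cell); all values must be `>= 0`.
#' @return same structure as `x` with total LOSS.
#' @export
convert_to_total_loss <- function(x, root_shoot_ratio) {
  r <- root_shoot_ratio
  if (any(r < 0, na.rm = TRUE)) stop("root-shoot ratio must be >= 0")
  if (inherits(x, "flux_grid")) {
    if (is.matrix(r) && !all(dim(r) == dim(x$values)))
      stop("ratio grid not conformable with the flux grid")
    x$values <- x$values * (1 + r)
    return(x)
  }
  if (!"loss" %in% names(x)) stop("no 'loss' column in plot table")
  x$loss <- x$loss * (1 + r)
  x
}

#' Aggregate plot records onto a regular observation grid
#'
#' Plots are binned into half-open cells `[lon, lon+res) x [lat, lat+res)`
#' so boundary plots land in exactly one cell; the cell value is the
#' unweighted mean of its member plots' LOSS, and cells without plots are
#' missing.
#'
#' @param plots plot data.frame with `lon`, `lat`, `loss`.
#' @param resolution cell size in degrees (default 0.25).
#' @param extent optional `c(lon_min, lon_max, lat_min, lat_max)` outer
#'   edges; defaults to the plots' bounding box snapped outward to the
#'   resolution.
#' @return list with `loss` (a `flux_grid`, Mg ha-1 yr-1) and `counts`
#'   (integer matrix of plots per cell).
#' @export
aggregate_to_grid <- function(plots, resolution = 0.25, extent = NULL) {
  if (!all(c("lon", "lat", "loss") %in% names(plots)))
    stop("plots need lon, lat and loss columns")
  if (is.null(extent)) {
    extent <- c(floor(min(plots$lon) / resolution) * resolution,
                ceiling(max(plots$lon) / resolution + 1e-9) * resolution,
                floor(min(plots$lat) / resolution) * resolution,
                ceiling(max(plots$lat) / resolution + 1e-9) * resolution)
  }
  g <- make_grid(extent, resolution, units = "Mg ha-1 yr-1",
                 variable = "LOSS")
  ij <- cell_index(g, plots$lon, plots$lat)
  key <- (ij[, 2] - 1L) * length(g$lat) + ij[, 1]
  sums <- tapply(plots$loss, key, sum)
  cnts <- tapply(plots$loss, key, length)
  counts <- matrix(0L, length(g$lat), length(g$lon))
  counts[as.integer(names(cnts))] <- as.integer(cnts)
  vals <- matrix(NA_real_, length(g$lat), length(g$lon))
  vals[as.integer(names(sums))] <- sums / cnts
  g$values <- vals
  list(loss = g, counts = counts)
}

#' Continental summaries of plot LOSS with a plot bootstrap
#'
#' Assigns each plot to a region, reports the plain mean and its standard
#' error, and estimates the sampling distribution of each regional mean by
#' bootstrap: `n_boot` draws of `round(frac * n)` plots without replacement
#' within the region (default 1000 draws of 90%).
#'
#' @param plots plot data.frame with `lon`, `lat`, `loss`.
#' @param regions a `region_set`.
#' @param n_boot bootstrap iterations.
#' @param frac subsample fraction per draw.
#' @param seed integer RNG seed.
#' @return data.frame (class `continental_summary`) with one row per region:
#'   `n`, `mean`, `se`, `boot_mean`, `boot_sd`, `boot_q025`, `boot_q975`,
#'   `flag` (`"ok"`, `"single_plot"`, or `"empty"`); the per-region bootstrap
#'   draws are kept in the `"boot"` attribute.
#' @export
continental_summary <- function(plots, regions, n_boot = 1000, frac = 0.9,
                                seed = 1) {
  stopifnot(inherits(regions, "region_set"))
  set.seed(seed)
  member <- region_membership(regions, lon = plots$lon, lat = plots$lat)
  boot_all <- list()
  rows <- lapply(regions$regions, function(rg) {
    x <- plots$loss[!is.na(member) & member == rg]
    n <- length(x)
    if (n == 0) {
      boot_all[[rg]] <<- numeric(0)
      return(data.frame(region = rg, n = 0L, mean = NA_real_, se = NA_real_,
                        boot_mean = NA_real_, boot_sd = NA_real_,
                        boot_q025 = NA_real_, boot_q975 = NA_real_,
                        flag = "empty"))
    }
    m <- round(frac * n)
    if (m < 1) m <- 1
    boots <- vapply(seq_len(n_boot),
                    function(b) mean(x[sample.int(n, m)]), 0)
    boot_all[[rg]] <<- boots
    data.frame(region = rg, n = n, mean = mean(x),
               se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
               boot_mean = mean(boots), boot_sd = stats::sd(boots),
               boot_q025 = stats::quantile(boots, 0.025, names = FALSE),
               boot_q975 = stats::quantile(boots, 0.975, names = FALSE),
               flag = if (n == 1) "single_plot" else "ok")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, boot = boot_all,
            class = c("continental_summary", "data.frame"))
}
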