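#' Construct a georeferenced flux grid
#'
#' A `flux_grid` is the basic raster container used throughout the package:
#' a matrix of values on a regular latitude/longitude grid with units,
#' variable name and averaging-period metadata. Rows are latitude bands
#' ordered north to south; columns are longitudes ordered west to east;
#' cells are centre-registered. Missing data are `NA`.
#'
#' @param values numeric matrix, `length(lat)` rows by `length(lon)` columns.
#' @param lat,lon numeric vectors of cell-centre coordinates (degrees).
#'   `lat` must be strictly decreasing within \[-90, 90\]; `lon` strictly
#'   increasing within \[-180, 180).
#' @param units unit tag, e.g. `"Mg ha-1 yr-1"` (biomass) or
#'   `"gC m-2 yr-1"` (carbon flux). Must be non-empty.
#' @param variable short variable name, e.g. `"LOSS"`.
#' @param period optional integer vector `c(start_year, end_year)`.
#' @return an object of class `flux_grid`.
#' @export
flux_grid <- function(values, lat, lon, units, variable = "",
                      period = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("dim(values) must be length(lat) x length(lon)")
  if (any(lat < -90 | lat > 90)) stop("lat outside [-90, 90]")
  if (length(lat) > 1 && any(diff(lat) >= 0))
    stop("lat must be strictly decreasing (north to south)")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("lon must be strictly increasing")
  if (!nzchar(units)) stop("'units' tag must be non-empty")
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite or NA")
  res <- grid_resolution(lat, lon)
  structure(list(values = values, lat = as.numeric(lat),
                 lon = as.numeric(lon), resolution = res, units = units,
                 variable = variable, period = period),
            class = "flux_grid")
}

grid_resolution <- function(lat, lon) {
  steps <- c(if (length(lat) > 1) abs(diff(lat)),
             if (length(lon) > 1) diff(lon))
  if (length(steps) == 0) return(NA_real_)
  res <- steps[1]
  if (any(abs(steps - res) > 1e-8))
    stop("grid spacing must be uniform in lat and lon")
  if (abs(360 / res - round(360 / res)) > 1e-8)
    stop("resolution must divide 360 evenly")
  res
}

#' Build an empty grid over a rectangular extent
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` outer edges, degrees.
#' @param resolution cell size in degrees; must divide the extent evenly.
#' @inheritParams flux_grid
#' @return a `flux_grid` of `NA` values.
#' @export
make_grid <- function(extent, resolution, units = "1", variable = "",
                      period = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  nlon <- (extent[2] - extent[1]) / resolution
  nlat <- (extent[4] - extent[3]) / resolution
  if (abs(nlon - round(nlon)) > 1e-8 || abs(nlat - round(nlat)) > 1e-8)
    stop("extent is not an integer number of cells at this resolution")
  nlon <- round(nlon); nlat <- round(nlat)
  lon <- extent[1] + (seq_len(nlon) - 0.5) * resolution
  lat <- extent[4] - (seq_len(nlat) - 0.5) * resolution
  flux_grid(matrix(NA_real_, nlat, nlon), lat, lon, units = units,
            variable = variable, period = period)
}

#' @export
print.flux_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<flux_grid> %s [%s]%s\n",
              if (nzchar(x$variable)) x$variable else "(unnamed)", x$units,
              if (!is.null(x$period))
                sprintf(" %d-%d", x$period[1], x$period[2]) else ""))
  cat(sprintf("  %d x %d cells at %s deg, lon [%.2f, %.2f], lat [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values), format(x$resolution),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  values: %.4g .. %.4g (%d missing)\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' Spherical cell areas of a grid
#'
#' Area of each cell on the sphere,
#' `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with
#' `R = 6371000` m, so a hemisphere-symmetric grid has symmetric areas and a
#' global grid sums to `4 * pi * R^2`.
#'
#' @param grid a `flux_grid` (only its coordinates are used).
#' @return numeric matrix of areas (m^2), same dimensions as the grid.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "flux_grid"))
  R <- 6371000
  res <- grid$resolution
  dlam <- res * pi / 180
  top <- pmin((grid$lat + res / 2), 90) * pi / 180
  bot <- pmax((grid$lat - res / 2), -90) * pi / 180
  band <- R^2 * dlam * (sin(top) - sin(bot))
  matrix(band, nrow = length(grid$lat), ncol = length(grid$lon))
}

#' Regrid a flux grid to a coarser or finer resolution
#'
#' Intensive variables only: coarsening takes the area-weighted mean of the
#' contributing fine cells, skipping missing ones; refining replicates the
#' parent value. Cells whose contributors are all missing stay missing. The
#' per-cell fraction of contributing (non-missing) fine cells is returned as
#' the `"coverage"` attribute after coarsening.
#'
#' @param grid a `flux_grid`.
#' @param target_resolution new cell size (degrees); must be an integer
#'   multiple or divisor of the current resolution.
#' @return a `flux_grid` at the target resolution.
#' @export
regrid <- function(grid, target_resolution) {
  stopifnot(inherits(grid, "flux_grid"))
  res <- grid$resolution
  if (target_resolution <= 0) stop("target resolution must be positive")
  up <- target_resolution / res
  if (abs(up - round(up)) < 1e-8 && round(up) >= 1) {
    f <- round(up)
    if (f == 1) return(grid)
    nlat <- length(grid$lat); nlon <- length(grid$lon)
    if (nlat %% f != 0 || nlon %% f != 0)
      stop("grid dimensions are not divisible by the coarsening factor")
    w <- cell_areas(grid)
    v <- grid$values
    wv <- ifelse(is.na(v), 0, v) * w
    wp <- ifelse(is.na(v), 0, w)
    sum_blocks <- function(m) {
      # fold rows then columns into f-sized blocks
      m1 <- rowsum(m, rep(seq_len(nlat / f), each = f))
      t(rowsum(t(m1), rep(seq_len(nlon / f), each = f)))
    }
    num <- sum_blocks(wv); den <- sum_blocks(wp)
    out <- num / den
    out[den == 0] <- NA_real_
    cov <- sum_blocks(matrix(as.numeric(!is.na(v)), nlat, nlon)) / f^2
    dimnames(out) <- dimnames(cov) <- NULL
    lat <- colMeans(matrix(grid$lat, nrow = f))
    lon <- colMeans(matrix(grid$lon, nrow = f))
    g <- flux_grid(out, lat, lon, units = grid$units,
                   variable = grid$variable, period = grid$period)
    attr(g, "coverage") <- cov
    return(g)
  }
  down <- res / target_resolution
  if (abs(down - round(down)) < 1e-8 && round(down) >= 1) {
    f <- round(down)
    v <- grid$values[rep(seq_along(grid$lat), each = f),
                     rep(seq_along(grid$lon), each = f), drop = FALSE]
    lat <- rep(grid$lat, each = f) +
      (res / 2 - (rep(seq_len(f), length(grid$lat)) - 0.5) * target_resolution)
    lon <- rep(grid$lon, each = f) -
      (res / 2 - (rep(seq_len(f), length(grid$lon)) - 0.5) * target_resolution)
    return(flux_grid(v, lat, lon, units = grid$units,
                     variable = grid$variable, period = grid$period))
  }
  stop(sprintf("incompatible resolutions: %s -> %s (need integer ratio)",
               format(res), format(target_resolution)))
}

#' Region definitions as longitude/latitude boxes
#'
#' Regions are unions of rectangular lon/lat boxes, one or more rows per
#' region. Boxes are half-open (`[min, max)`) so that adjacent regions do not
#' overlap. The shipped default covers the four continents used for
#' continental aggregation: North America, South America, Africa, and Asia &
#' Australia; these are deliberately simple and editable.
#'
#' @param boxes data.frame with columns `region`, `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`.
#' @return object of class `region_set`.
#' @export
region_set <- function(boxes) {
  need <- c("region", "lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(boxes)))
    stop("boxes must have columns: ", paste(need, collapse = ", "))
  structure(list(boxes = boxes,
                 regions = unique(as.character(boxes$region))),
            class = "region_set")
}

#' @rdname region_set
#' @export
continental_regions <- function() {
  region_set(data.frame(
    region = c("North America", "South America", "Africa",
               "Asia & Australia", "Asia & Australia"),
    lon_min = c(-170, -95, -20, 60, -180),
    lon_max = c(-50, -30, 55, 180, -170),
    lat_min = c(13, -60, -40, -50, -50),
    lat_max = c(75, 13, 40, 75, 75)))
}

#' Assign grid cells or points to regions
#'
#' @param regions a `region_set`.
#' @param grid a `flux_grid` (cell centres are classified), or `NULL` when
#'   `lon`/`lat` point vectors are given.
#' @param lon,lat point coordinates, used when `grid` is `NULL`.
#' @return for a grid, a character matrix of region names (`NA` where no
#'   region matches); for points, a character vector. Overlapping region
#'   definitions are an error.
#' @export
region_membership <- function(regions, grid = NULL, lon = NULL, lat = NULL) {
  stopifnot(inherits(regions, "region_set"))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "flux_grid"))
    lon <- rep(grid$lon, each = length(grid$lat))
    lat <- rep(grid$lat, length(grid$lon))
  }
  out <- rep(NA_character_, length(lon))
  hits <- integer(length(lon))
  for (i in seq_len(nrow(regions$boxes))) {
    b <- regions$boxes[i, ]
    inb <- lon >= b$lon_min & lon < b$lon_max &
      lat >= b$lat_min & lat < b$lat_max
    newly <- inb & (is.na(out) | out == b$region)
    if (any(inb & !is.na(out) & out != b$region))
      stop("regions overlap at some cells; definitions must be disjoint")
    out[newly] <- as.character(b$region)
    hits[inb] <- hits[inb] + 1L
  }
  if (!is.null(grid)) out <- matrix(out, length(grid$lat), length(grid$lon))
  out
}

#' Intersect mask layers into a forest mask
#'
#' A cell counts as natural forest only if every layer's predicate passes
#' (e.g. tree cover, human footprint, burn fraction, managed land). Layers
#' are supplied already thresholded, as logical matrices; the mask records
#' its provenance, and adding a layer can only remove cells.
#'
#' @param layers named list of logical matrices, co-registered.
#' @return logical matrix of class `forest_mask` with a `"provenance"`
#'   attribute listing the layer names.
#' @export
build_forest_mask <- function(layers) {
  if (length(layers) == 0) stop("at least one mask layer is required")
  nm <- names(layers)
  if (is.null(nm) || any(!nzchar(nm))) stop("all mask layers must be named")
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]])) stop("missing mask layer: ", nm[i])
    if (!is.logical(layers[[i]]))
      stop("mask layer '", nm[i], "' must be logical")
    if (!identical(dim(layers[[i]]), dim(layers[[1]])))
      stop("mask layer '", nm[i], "' is not co-registered with '",
           nm[1], "'")
  }
  m <- Reduce(`&`, layers)
  m[is.na(m)] <- FALSE
  structure(m, class = c("forest_mask", class(m)), provenance = nm)
}

# unit conversion to gC m-2 yr-1; biomass units use a carbon fraction
flux_to_gc_m2 <- function(values, units, carbon_fraction = 0.5) {
  u <- gsub("\\s+", " ", trimws(units))
  if (u %in% c("gC m-2 yr-1", "gC m-2 y-1")) return(values)
  if (u %in% c("Mg ha-1 yr-1", "Mg ha-1 y-1")) {
    # 1 Mg biomass / ha = 100 g / m2, times carbon fraction
    return(values * 100 * carbon_fraction)
  }
  if (u %in% c("MgC ha-1 yr-1", "MgC ha-1 y-1")) return(values * 100)
  stop("unit tag not convertible to gC m-2 yr-1: '", units, "'")
}

#' Aggregate a flux grid to regional totals and means
#'
#' Converts the flux to gC m-2 yr-1, multiplies by spherical cell area, and
#' sums over the masked-in cells of each region (Pg C yr-1). Missing cells
#' are skipped and reported via a coverage fraction; means are area-weighted.
#'
#' @param grid a `flux_grid` whose units are convertible to gC m-2 yr-1.
#' @param areas cell-area matrix from [cell_areas()]; computed if `NULL`.
#' @param mask logical matrix of cells to include (e.g. a forest mask), or
#'   `NULL` for all cells.
#' @param regions a `region_set`; `NULL` aggregates the whole domain as one
#'   region called `"domain"`.
#' @param carbon_fraction carbon fraction applied to biomass units
#'   (default 0.5).
#' @return data.frame with one row per region: `total_PgC` (Pg C yr-1),
#'   `mean_flux` (gC m-2 yr-1, area-weighted), `area_m2`, `n_cells`,
#'   `coverage` (fraction of masked-in cells that had data). Regions with no
#'   masked cells get total 0 and `NA` mean.
#' @export
aggregate_regional <- function(grid, areas = NULL, mask = NULL,
                               regions = NULL, carbon_fraction = 0.5) {
  stopifnot(inherits(grid, "flux_grid"))
  if (is.null(areas)) areas <- cell_areas(grid)
  if (!all(dim(areas) == dim(grid$values)))
    stop("areas not conformable with grid")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(grid$values), ncol(grid$values))
  if (!all(dim(mask) == dim(grid$values)))
    stop("mask not conformable with grid")
  flux <- flux_to_gc_m2(grid$values, grid$units, carbon_fraction)
  if (is.null(regions)) {
    member <- matrix("domain", nrow(flux), ncol(flux))
    region_names <- "domain"
  } else {
    member <- region_membership(regions, grid)
    region_names <- regions$regions
  }
  out <- lapply(region_names, function(rg) {
    sel <- mask & !is.na(member) & member == rg
    n <- sum(sel)
    ok <- sel & !is.na(flux)
    tot <- sum(flux[ok] * areas[ok]) / 1e15
    a <- sum(areas[ok])
    data.frame(region = rg, total_PgC = tot,
               mean_flux = if (a > 0) sum(flux[ok] * areas[ok]) / a
                           else NA_real_,
               area_m2 = a, n_cells = n,
               coverage = if (n > 0) sum(ok) / n else NA_real_)
  })
  do.call(rbind, out)
}

#' Write / read a flux grid as delimited text
#'
#' Long-format CSV (`lat,lon,value`) with `#`-prefixed metadata header lines
#' carrying the variable name, units, resolution and period, so grids round-
#' trip exactly through plain text.
#'
#' @param grid a `flux_grid`.
#' @param path file path.
#' @export
write_flux_grid <- function(grid, path) {
  stopifnot(inherits(grid, "flux_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# variable: %s", grid$variable),
               sprintf("# units: %s", grid$units),
               sprintf("# resolution: %.10g", grid$resolution),
               sprintf("# period: %s",
                       if (is.null(grid$period)) "NA"
                       else paste(grid$period, collapse = "-"))), con)
  df <- data.frame(lat = rep(grid$lat, length(grid$lon)),
                   lon = rep(grid$lon, each = length(grid$lat)),
                   value = as.vector(grid$values))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_grid
#' @export
read_flux_grid <- function(path) {
  hdr <- readLines(path, n = 4)
  meta <- sub("^# [a-z]+: ", "", hdr)
  df <- utils::read.csv(path, comment.char = "#")
  lat <- sort(unique(df$lat), decreasing = TRUE)
  lon <- sort(unique(df$lon))
  v <- matrix(NA_real_, length(lat), length(lon))
  v[cbind(match(df$lat, lat), match(df$lon, lon))] <- df$value
  period <- if (meta[4] == "NA") NULL
            else as.integer(strsplit(meta[4], "-", fixed = TRUE)[[1]])
  flux_grid(v, lat, lon, units = meta[2], variable = meta[1],
            period = period)
}
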