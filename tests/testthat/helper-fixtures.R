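# Shared fixtures, built once per test run. The small world/ensemble pair is
# reused across files; tests that need different generator settings build
# their own.

small_world <- function() {
  if (is.null(.fixtures$world))
    .fixtures$world <- generate_world(seed = 101)
  .fixtures$world
}

small_ensemble <- function() {
  if (is.null(.fixtures$ensemble))
    .fixtures$ensemble <- simulate_ensemble(small_world(),
                                            coupling_spec(), seed = 202)
  .fixtures$ensemble
}

# two-region partition of the default synthetic domain
halves_regions <- function(extent = c(-70, -60, -15, -5)) {
  mid <- (extent[1] + extent[2]) / 2
  region_set(data.frame(region = c("west", "east"),
                        lon_min = c(extent[1], mid),
                        lon_max = c(mid, extent[2]),
                        lat_min = extent[3], lat_max = extent[4]))
}

# tiny grid centred on the equator so 2x2 blocks have equal cell areas
equatorial_grid <- function(values, res = 0.25) {
  n <- nrow(values)
  stopifnot(n %% 2 == 0, ncol(values) %% 2 == 0)
  lat <- (n / 2 - seq_len(n) + 0.5) * res
  lon <- (seq_len(ncol(values)) - 0.5) * res
  flux_grid(values, lat, lon, units = "Mg ha-1 yr-1", variable = "LOSS")
}

.fixtures <- new.env(parent = emptyenv())
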