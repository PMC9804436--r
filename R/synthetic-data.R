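#' Simulation specification for one species
#'
#' Describes the ground-truth stranding process for a synthetic species: a
#' linear poleward drift of the distribution with Gaussian event-level
#' scatter. In year `t` (1-based) each stranding event has poleward distance
#' `a + b * t + rnorm(1, 0, sigma)`.
#'
#' @param species_id species label.
#' @param slope_b true poleward drift, km/year.
#' @param intercept_a poleward distance at year 1, km.
#' @param sd_sigma event-level SD of poleward distance within a year, km.
#' @param annual_n events per year: a single count or a vector of length
#'   `n_years`; zeros give empty years.
#' @param climatic_category one of `"warm"`, `"cool"`, `"arctic"`,
#'   `"cosmopolitan"`.
#' @param trailing_edge does the species' trailing edge fall in the study
#'   region (adds the q05 statistic downstream)?
#' @return object of class `species_sim_spec`.
#' @export
species_sim_spec <- function(species_id, slope_b, intercept_a, sd_sigma,
                             annual_n, climatic_category = "warm",
                             trailing_edge = FALSE) {
  assert_number(slope_b, "slope_b")
  assert_number(intercept_a, "intercept_a")
  assert_number(sd_sigma, "sd_sigma", lower = 0)
  if (!is.numeric(annual_n) || any(!is.finite(annual_n)) || any(annual_n < 0) ||
      any(annual_n != round(annual_n))) {
    stop("`annual_n` must be non-negative integer count(s)", call. = FALSE)
  }
  climatic_category <- match.arg(climatic_category, climatic_categories())
  structure(
    list(species_id = as.character(species_id), slope_b = slope_b,
         intercept_a = intercept_a, sd_sigma = sd_sigma,
         annual_n = as.integer(annual_n),
         climatic_category = climatic_category,
         trailing_edge = isTRUE(trailing_edge)),
    class = "species_sim_spec"
  )
}

#' Synthetic raster world
#'
#' A rectangular latitude/longitude grid holding an idealised meridional
#' coastline: the westernmost `land_cols` columns are land, the next
#' `shelf_cols` columns are the continental shelf, and the remaining columns
#' are off-shelf ocean. The along-shelf distance origin sits at the
#' south-western corner of the shelf (the stand-in for the southern end of
#' mainland Florida). Rows are latitude (south to north), so the along-shelf
#' coordinate increases straight poleward; a realistic curvilinear coastline
#' is deliberately out of scope.
#'
#' @param n_years number of annual time steps (calendar years start at
#'   `start_year`); at least 3.
#' @param start_year first calendar year; default 1996.
#' @param n_rows,n_cols grid shape (rows = latitude).
#' @param cell_km cell edge length in km (sets the latitude spacing;
#'   longitude spacing is `cell_km` at the grid's central latitude).
#' @param land_cols,shelf_cols number of land and shelf columns.
#' @param lat0,lon0 coordinates of the south-west cell center, decimal
#'   degrees.
#' @param n_counties number of synthetic coastal counties spaced evenly
#'   along the coastline (used by [gen_census()] and for county labels on
#'   generated strandings).
#' @return object of class `world_spec`.
#' @export
world_spec <- function(n_years = 25, start_year = 1996,
                       n_rows = 220, n_cols = 24, cell_km = 10,
                       land_cols = 6, shelf_cols = 12,
                       lat0 = 25.0, lon0 = -81.0, n_counties = 20) {
  assert_number(n_years, "n_years", lower = 3)
  assert_number(cell_km, "cell_km", lower = 1e-9)
  stopifnot(n_rows >= 2, n_cols >= 2, land_cols >= 1,
            shelf_cols >= 1, land_cols + shelf_cols <= n_cols,
            n_counties >= 1)
  lat <- lat0 + (seq_len(n_rows) - 1) * cell_km / KM_PER_DEG
  lat_mid <- mean(range(lat))
  dlon <- cell_km / (KM_PER_DEG * cos(lat_mid * pi / 180))
  lon <- lon0 + (seq_len(n_cols) - 1) * dlon
  structure(
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_km = cell_km, land_cols = as.integer(land_cols),
         shelf_cols = as.integer(shelf_cols),
         lat = lat, lon = lon, coast_col = as.integer(land_cols + 1L),
         origin = c(row = 1L, col = as.integer(land_cols + 1L)),
         max_distance_km = (n_rows - 1) * cell_km,
         n_counties = as.integer(n_counties)),
    class = "world_spec"
  )
}

#' @noRd
world_years <- function(world) world$start_year + seq_len(world$n_years) - 1L

# county index for an along-shelf distance; counties partition [0, Lmax]
#' @noRd
county_of_distance <- function(world, d) {
  span <- world$max_distance_km / world$n_counties
  idx <- pmin(pmax(floor(d / span) + 1, 1), world$n_counties)
  sprintf("county_%02d", idx)
}

#' Generate synthetic stranding events
#'
#' Draws `annual_n[t]` events for each year `t = 1..n_years` with poleward
#' distance `a + b * t + rnorm(., 0, sigma)` and places each event on the
#' synthetic coastline at that along-shelf distance (deterministically: no
#' cross-shore scatter unless requested). Distances falling outside the
#' world are placed at the domain edge but keep their unclamped ground-truth
#' value in `true_distance_km`.
#'
#' @param spec [species_sim_spec()].
#' @param world [world_spec()].
#' @param seed integer seed (RNG state is restored afterwards).
#' @param cross_shore_sd_km optional Gaussian cross-shore scatter applied to
#'   longitude, km; default 0.
#' @return tibble with one row per event: `event_id`, `species_id`, `year`,
#'   `date`, `latitude`, `longitude`, `state`, `county`, `description`,
#'   `true_distance_km`, `placed_distance_km`.
#' @export
gen_strandings <- function(spec, world, seed = NULL, cross_shore_sd_km = 0) {
  stopifnot(inherits(spec, "species_sim_spec"), inherits(world, "world_spec"))
  T_ <- world$n_years
  if (T_ < 3L) stop("need at least 3 years to estimate a trend", call. = FALSE)
  ann <- spec$annual_n
  if (length(ann) == 1L) ann <- rep(ann, T_)
  if (length(ann) != T_) {
    stop("`annual_n` must have length 1 or n_years (", T_, ")", call. = FALSE)
  }
  if (any(ann < 0)) stop("`annual_n` entries must be >= 0", call. = FALSE)
  with_seed_(seed, {
    t_idx <- rep(seq_len(T_), times = ann)
    n_tot <- length(t_idx)
    d_true <- spec$intercept_a + spec$slope_b * t_idx +
      stats::rnorm(n_tot, 0, spec$sd_sigma)
    d_placed <- pmin(pmax(d_true, 0), world$max_distance_km)
    lat <- world$lat[1] + d_placed / KM_PER_DEG
    lon <- rep(world$lon[world$coast_col], n_tot)
    if (cross_shore_sd_km > 0 && n_tot > 0) {
      lon <- lon + stats::rnorm(n_tot, 0, cross_shore_sd_km) /
        (KM_PER_DEG * cos(lat * pi / 180))
    }
    yrs <- world_years(world)[t_idx]
    tibble::tibble(
      event_id = sprintf("%s_%05d", spec$species_id, seq_len(n_tot)),
      species_id = spec$species_id,
      year = yrs,
      date = as.Date(sprintf("%d-07-01", yrs)),
      latitude = lat,
      longitude = lon,
      state = "SYN",
      county = county_of_distance(world, d_placed),
      description = "synthetic coastline placement",
      true_distance_km = d_true,
      placed_distance_km = d_placed
    )
  })
}

#' Generate a synthetic annual-mean SST cube
#'
#' Builds `SST(row, col, t) = base + spatial_gradient * northward_km +
#' temporal_gradient * (t - 1) + noise` on the world grid, with land cells
#' missing. The time-mean field therefore carries a meridional spatial
#' gradient of exactly `spatial_gradient` degC/km, so in the noiseless case
#' the climate velocity is `temporal_gradient / spatial_gradient` km/year on
#' every interior sea cell.
#'
#' @param world [world_spec()].
#' @param temporal_gradient degC/year; a scalar or an `n_rows x n_cols`
#'   matrix for spatially varying warming.
#' @param spatial_gradient meridional SST gradient, degC/km.
#' @param noise_sd iid Gaussian noise SD per cell-year, degC; must be >= 0.
#' @param base_sst SST at the origin in year 1, degC.
#' @param seed integer seed.
#' @return an [sst_cube()].
#' @export
gen_sst_cube <- function(world, temporal_gradient = 0.05,
                         spatial_gradient = 0.01, noise_sd = 0,
                         base_sst = 12, seed = NULL) {
  stopifnot(inherits(world, "world_spec"))
  assert_number(noise_sd, "noise_sd", lower = 0)
  nr <- world$n_rows; nc <- world$n_cols; T_ <- world$n_years
  gt <- temporal_gradient
  if (length(gt) == 1L) gt <- matrix(gt, nr, nc)
  stopifnot(all(dim(gt) == c(nr, nc)))
  north_km <- (seq_len(nr) - 1) * world$cell_km
  base <- base_sst + matrix(spatial_gradient * north_km, nr, nc)
  arr <- array(NA_real_, c(nr, nc, T_))
  with_seed_(seed, {
    for (t in seq_len(T_)) {
      slab <- base + gt * (t - 1)
      if (noise_sd > 0) slab <- slab + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      arr[, , t] <- slab
    }
  })
  land <- world_land_mask(world)
  arr[rep(land, times = T_)] <- NA_real_
  sst_cube(arr, lat = world$lat, lon = world$lon, years = world_years(world))
}

#' @noRd
world_land_mask <- function(world) {
  m <- matrix(FALSE, world$n_rows, world$n_cols)
  m[, seq_len(world$land_cols)] <- TRUE
  m
}

#' @noRd
world_offshelf_mask <- function(world) {
  m <- matrix(TRUE, world$n_rows, world$n_cols)
  shelf <- world$land_cols + seq_len(world$shelf_cols)
  m[, shelf] <- FALSE
  m[, seq_len(world$land_cols)] <- FALSE   # land handled by land mask
  m
}

#' Generate a synthetic coastal county census table
#'
#' County centroids are spaced evenly along the coastline; the percent
#' population change 2000 to 2020 follows
#' `alpha + beta * poleward_distance + noise`. `pop_2020` is stored
#' unrounded so that `pct_change` satisfies its defining identity exactly.
#'
#' @param world [world_spec()].
#' @param n_counties number of counties; default taken from the world.
#' @param alpha baseline percent change; default 10.
#' @param beta slope of percent change per km of poleward distance.
#' @param noise_sd Gaussian noise on percent change.
#' @param pop_2000 baseline county population (scalar), persons.
#' @param seed integer seed.
#' @return tibble: `county`, `latitude`, `longitude`, `poleward_distance_km`,
#'   `pop_2000`, `pop_2020`, `pct_change`.
#' @export
gen_census <- function(world, n_counties = world$n_counties, alpha = 10,
                       beta = -0.01, noise_sd = 0, pop_2000 = 1e5,
                       seed = NULL) {
  stopifnot(inherits(world, "world_spec"), n_counties >= 3)
  span <- world$max_distance_km / n_counties
  d <- (seq_len(n_counties) - 0.5) * span
  with_seed_(seed, {
    pct <- alpha + beta * d +
      if (noise_sd > 0) stats::rnorm(n_counties, 0, noise_sd) else 0
    tibble::tibble(
      county = sprintf("county_%02d", seq_len(n_counties)),
      latitude = world$lat[1] + d / KM_PER_DEG,
      longitude = world$lon[world$coast_col],
      poleward_distance_km = d,
      pop_2000 = pop_2000,
      pop_2020 = pop_2000 * (1 + pct / 100),
      pct_change = pct
    )
  })
}

#' Gazetteer (county -> centroid) from a census table
#'
#' @param census output of [gen_census()] or any table with `county`,
#'   `latitude`, `longitude`.
#' @return tibble `county`, `latitude`, `longitude`.
#' @export
gazetteer_from_census <- function(census) {
  tibble::as_tibble(census[, c("county", "latitude", "longitude")])
}

#' Write a stranding fixture as CSV plus a ground-truth JSON sidecar
#'
#' The CSV matches the Level-A input schema expected by [read_level_a()];
#' the sidecar records the generating parameters so downstream recovery can
#' be checked against the truth.
#'
#' @param records tibble from [gen_strandings()].
#' @param spec the generating [species_sim_spec()].
#' @param path CSV path; the sidecar goes to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_stranding_fixture <- function(records, spec, path) {
  out <- records
  out$date <- as.character(out$date)
  utils::write.csv(out, path, row.names = FALSE)
  truth <- list(species_id = spec$species_id, slope_b = spec$slope_b,
                intercept_a = spec$intercept_a, sd_sigma = spec$sd_sigma,
                annual_n = spec$annual_n,
                climatic_category = spec$climatic_category,
                trailing_edge = spec$trailing_edge,
                n_events = nrow(records))
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
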