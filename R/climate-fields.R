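#' Annual-mean SST cube
#'
#' Container for a latitude x longitude x year array of annual-mean
#' sea-surface temperature with its coordinate vectors. Cell sizes in km are
#' derived from the coordinates (longitude spacing scaled by the cosine of
#' latitude) but can be overridden for idealised planar fixtures.
#'
#' @param data numeric array `[n_lat, n_lon, n_year]`; land/missing cells NA.
#' @param lat,lon strictly monotone coordinate vectors (decimal degrees).
#' @param years integer vector of years (>= 3).
#' @param dx_km optional per-row east-west cell size, km (length `n_lat`).
#' @param dy_km optional north-south cell size, km (scalar).
#' @return object of class `sst_cube`.
#' @export
sst_cube <- function(data, lat, lon, years, dx_km = NULL, dy_km = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  stopifnot(length(lat) == d[1], length(lon) == d[2], length(years) == d[3])
  if (length(years) < 3L) stop("an SST cube needs at least 3 years", call. = FALSE)
  mono <- function(v) all(diff(v) > 0) || all(diff(v) < 0)
  if (!mono(lat) || !mono(lon)) {
    stop("`lat` and `lon` must be strictly monotone", call. = FALSE)
  }
  if (is.null(dy_km)) dy_km <- abs(mean(diff(lat))) * KM_PER_DEG
  if (is.null(dx_km)) {
    dx_km <- abs(mean(diff(lon))) * KM_PER_DEG * cos(lat * pi / 180)
  }
  if (length(dx_km) == 1L) dx_km <- rep(dx_km, d[1])
  structure(
    list(data = data, lat = lat, lon = lon, years = as.integer(years),
         dx_km = dx_km, dy_km = dy_km),
    class = "sst_cube"
  )
}

#' @export
print.sst_cube <- function(x, ...) {
  cat(sprintf("SST cube: %d x %d cells, years %d-%d (%d), %.1f%% missing\n",
              dim(x$data)[1], dim(x$data)[2], min(x$years), max(x$years),
              length(x$years), 100 * mean(is.na(x$data))))
  invisible(x)
}

#' Per-cell temporal SST gradient
#'
#' OLS slope of SST against year for every cell, degC/year. Cells with fewer
#' than 3 non-missing years are masked.
#'
#' @param cube [sst_cube()].
#' @return matrix `[n_lat, n_lon]` of slopes (NA where masked).
#' @export
temporal_gradient <- function(cube) {
  stopifnot(inherits(cube, "sst_cube"))
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  # center years for numerical conditioning; the OLS slope is invariant
  yr <- as.numeric(cube$years) - mean(cube$years)
  V <- !is.na(X)
  X0 <- X; X0[!V] <- 0
  n <- rowSums(V)
  Sx <- V %*% yr
  Sy <- rowSums(X0)
  Sxy <- X0 %*% yr
  Sxx <- V %*% yr^2
  denom <- Sxx - Sx^2 / n
  slope <- (Sxy - Sx * Sy / n) / denom
  slope[n < 3 | denom <= 0] <- NA_real_
  matrix(slope, d[1], d[2])
}

#' Per-cell spatial SST gradient magnitude
#'
#' Works on the time-mean field. In each 3 x 3 neighborhood the west-east
#' component is the mean of the row-wise central differences (scaled by the
#' local east-west cell size, which shrinks with the cosine of latitude) and
#' the south-north component the mean of the column-wise central
#' differences; the gradient is `sqrt(gx^2 + gy^2)` in degC/km. Cells with
#' fewer than `min_neighbors` valid neighbors, or lacking a defined central
#' difference in either direction, are masked.
#'
#' @param cube [sst_cube()] (time-averaged internally).
#' @param min_neighbors minimum valid cells among the 8 neighbors; default 3.
#' @return list with matrices `gx`, `gy`, `magnitude`.
#' @export
spatial_gradient <- function(cube, min_neighbors = 3) {
  stopifnot(inherits(cube, "sst_cube"))
  Tm <- apply(cube$data, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  nr <- nrow(Tm); nc <- ncol(Tm)
  cd_x <- matrix(NA_real_, nr, nc)
  if (nc >= 3) {
    cd_x[, 2:(nc - 1)] <- (Tm[, 3:nc] - Tm[, 1:(nc - 2)]) / (2 * cube$dx_km)
  }
  cd_y <- matrix(NA_real_, nr, nc)
  if (nr >= 3) {
    cd_y[2:(nr - 1), ] <- (Tm[3:nr, ] - Tm[1:(nr - 2), ]) / (2 * cube$dy_km)
  }
  gx <- navg3_(cd_x, margin = 1)   # average central differences over the 3 rows
  gy <- navg3_(cd_y, margin = 2)   # ... over the 3 columns
  nb <- neighbor_count_(!is.na(Tm))
  bad <- is.na(gx) | is.na(gy) | nb < min_neighbors
  gx[bad] <- NA_real_; gy[bad] <- NA_real_
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# mean over a length-3 window of rows (margin = 1) or columns (margin = 2),
# NA-aware; edge windows are truncated
#' @noRd
navg3_ <- function(M, margin) {
  v <- !is.na(M)
  M0 <- M; M0[!v] <- 0
  shift <- function(A, k) {
    nr <- nrow(A); nc <- ncol(A)
    out <- matrix(0, nr, nc)
    if (margin == 1) {
      if (k == -1) out[2:nr, ] <- A[1:(nr - 1), ]
      if (k == 0) out <- A
      if (k == 1) out[1:(nr - 1), ] <- A[2:nr, ]
    } else {
      if (k == -1) out[, 2:nc] <- A[, 1:(nc - 1)]
      if (k == 0) out <- A
      if (k == 1) out[, 1:(nc - 1)] <- A[, 2:nc]
    }
    out
  }
  s <- shift(M0, -1) + shift(M0, 0) + shift(M0, 1)
  n <- shift(v * 1, -1) + shift(v * 1, 0) + shift(v * 1, 1)
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# number of valid cells among the 8 neighbors
#' @noRd
neighbor_count_ <- function(valid) {
  nr <- nrow(valid); nc <- ncol(valid)
  v <- matrix(0, nr + 2, nc + 2)
  v[2:(nr + 1), 2:(nc + 1)] <- valid * 1
  tot <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    tot <- tot + v[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  tot
}

#' Gradient-based (scalar) climate velocity
#'
#' `v = temporal gradient / spatial gradient magnitude` (degC/year over
#' degC/km = km/year), signed by the temporal gradient: positive velocities
#' mean isotherms move poleward (warming), negative equatorward. Cells whose
#' spatial gradient falls below `eps` are masked rather than allowed to
#' produce unbounded velocities.
#'
#' @param g_t temporal-gradient matrix (degC/year).
#' @param grad_mag spatial-gradient magnitude matrix (degC/km).
#' @param eps gradient floor, degC/km; default 1e-5.
#' @return list with `velocity` matrix (km/year) and logical `valid` mask.
#' @export
climate_velocity <- function(g_t, grad_mag, eps = 1e-5) {
  if (!all(dim(g_t) == dim(grad_mag))) {
    stop("temporal and spatial gradient fields must have the same shape",
         call. = FALSE)
  }
  valid <- is.finite(g_t) & is.finite(grad_mag) & grad_mag >= eps
  v <- matrix(NA_real_, nrow(g_t), ncol(g_t))
  v[valid] <- g_t[valid] / grad_mag[valid]
  list(velocity = v, valid = valid)
}

#' Regional summary of a cell field
#'
#' Median and quartiles over the valid cells of a region.
#'
#' @param field numeric matrix (NA = masked).
#' @param region_mask logical matrix selecting the region; NULL = all cells.
#' @param area_weights optional non-negative weight matrix (e.g.
#'   `cos(latitude)` for cell area); quantiles are unweighted by default.
#' @return tibble with `median`, `q25`, `q75`, `n_cells`.
#' @export
regional_summary <- function(field, region_mask = NULL, area_weights = NULL) {
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(field), ncol(field))
  vals <- field[region_mask & is.finite(field)]
  if (length(vals) == 0) stop("region contains no valid cells", call. = FALSE)
  if (is.null(area_weights)) {
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  } else {
    w <- area_weights[region_mask & is.finite(field)]
    q <- weighted_quantile_(vals, w, c(0.25, 0.5, 0.75))
  }
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n_cells = length(vals))
}

#' @noRd
weighted_quantile_ <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Regional SST anomaly series and trend
#'
#' Annual regional mean SST minus the baseline climatology (the mean of the
#' regional annual means over the baseline window, by default the full
#' record), with the OLS trend of the anomaly series.
#'
#' @param cube [sst_cube()].
#' @param region_mask logical matrix; NULL = all cells.
#' @param baseline_years years defining the climatology; default all.
#' @param area_weighted weight cells by `cos(latitude)` when averaging.
#' @return list with `series` (tibble `year`, `sst`, `anomaly`) and `trend`
#'   (a [fit_trend()] of anomaly on year).
#' @export
sst_anomaly_series <- function(cube, region_mask = NULL, baseline_years = NULL,
                               area_weighted = FALSE) {
  stopifnot(inherits(cube, "sst_cube"))
  d <- dim(cube$data)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, d[1], d[2])
  if (is.null(baseline_years)) baseline_years <- cube$years
  if (!all(baseline_years %in% cube$years)) {
    stop("baseline window must lie within the cube's years", call. = FALSE)
  }
  w <- if (area_weighted) {
    matrix(cos(cube$lat * pi / 180), d[1], d[2])
  } else {
    matrix(1, d[1], d[2])
  }
  ann <- vapply(seq_len(d[3]), function(t) {
    slab <- cube$data[, , t]
    ok <- region_mask & is.finite(slab)
    if (!any(ok)) return(NA_real_)
    sum(slab[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  if (all(is.na(ann))) stop("region contains no valid cells", call. = FALSE)
  clim <- mean(ann[cube$years %in% baseline_years], na.rm = TRUE)
  series <- tibble::tibble(year = cube$years, sst = ann, anomaly = ann - clim)
  list(series = series, trend = fit_trend(series, response = "anomaly"))
}

#' Write / read an SST cube as long-format CSV
#'
#' Plain-text serialization (`lat, lon, year, sst`) used for fixtures and
#' pipeline outputs.
#'
#' @param cube [sst_cube()].
#' @param path CSV path.
#' @return `path` (write) or an [sst_cube()] (read).
#' @export
write_sst_cube_csv <- function(cube, path) {
  d <- dim(cube$data)
  df <- expand.grid(lat = cube$lat, lon = cube$lon, year = cube$years,
                    KEEP.OUT.ATTRS = FALSE)
  df$sst <- as.vector(cube$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sst_cube_csv
#' @export
read_sst_cube_csv <- function(path) {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  years <- sort(unique(df$year))
  arr <- array(NA_real_, c(length(lat), length(lon), length(years)))
  arr[cbind(match(df$lat, lat), match(df$lon, lon), match(df$year, years))] <- df$sst
  sst_cube(arr, lat, lon, years)
}
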