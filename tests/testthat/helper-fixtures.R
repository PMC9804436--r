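# shared fixtures and independent oracles

KM_PER_DEG_test <- function() 111.32

tiny_world <- function(n_years = 25, n_rows = 120, cell_km = 10, ...) {
  world_spec(n_years = n_years, n_rows = n_rows, n_cols = 12, cell_km = cell_km,
             land_cols = 3, shelf_cols = 6, n_counties = 10, ...)
}

# random barrier world on a 15x15 grid; origin (1,1) kept traversable
random_barrier_grid <- function(seed, nr = 15, nc = 15, p_barrier = 0.3) {
  withr::with_seed(seed, {
    land <- matrix(stats::runif(nr * nc) < p_barrier, nr, nc)
    land[1, 1] <- FALSE
    lat <- 30 + (seq_len(nr) - 1) * 0.1
    lon <- -75 + (seq_len(nc) - 1) * 0.1
    shelf_grid(lat, lon, land)
  })
}

# independent shortest-path oracle: Bellman-Ford edge relaxation to a fixed
# point over the same 8-connected weighted graph
bf_distance <- function(grid, origin = c(1L, 1L)) {
  nr <- length(grid$lat); nc <- length(grid$lon)
  trav <- grid$traversable
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!trav[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !trav[rr, cc]) next
      wt <- if (dc == 0) {
        grid$dy_km
      } else {
        dx <- (grid$dx_km[r] + grid$dx_km[rr]) / 2
        if (dr == 0) dx else sqrt(dx^2 + grid$dy_km^2)
      }
      from <- c(from, id(r, c)); to <- c(to, id(rr, cc)); w <- c(w, wt)
    }
  }
  dist <- rep(Inf, nr * nc)
  dist[id(origin[1], origin[2])] <- 0
  repeat {
    cand <- dist[from] + w
    best <- tapply(cand, to, min)
    idx <- as.integer(names(best))
    nd <- dist
    nd[idx] <- pmin(nd[idx], best)
    if (identical(nd, dist)) break
    dist <- nd
  }
  m <- matrix(dist, nr, nc)
  m[!trav] <- NA_real_
  m
}

# closed-form OLS slope oracle (centered covariance formula)
ols_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# independent haversine (explicit formula; same 6378.137 km radius as the
# package's distance backend so thresholds are comparable)
haversine_oracle <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6378.137 * asin(pmin(1, sqrt(a)))
}
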