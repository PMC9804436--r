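test_that("straight open channel gives distance k * cell along the axis", {
  lat <- 30 + (0:19) * (1 / KM_PER_DEG_test())
  lon <- -75 + (0:2) * (1 / KM_PER_DEG_test())
  land <- matrix(FALSE, 20, 3)
  land[, c(1, 3)] <- TRUE   # 1-cell-wide channel up column 2
  g <- shelf_grid(lat, lon, land)
  g$dy_km <- 1
  f <- build_distance_field(g, origin = c(1, 2))
  expect_equal(f$distance_km[, 2], 0:19, tolerance = 1e-12)
})

test_that("U-shaped barrier detour equals the Bellman-Ford oracle exactly", {
  lat <- 30 + (0:19) * 0.1
  lon <- -75 + (0:19) * 0.1
  land <- matrix(FALSE, 20, 20)
  land[5:15, 5] <- TRUE; land[15, 5:15] <- TRUE; land[5:15, 15] <- TRUE
  g <- shelf_grid(lat, lon, land)
  f <- build_distance_field(g, origin = c(1, 1))
  oracle <- bf_distance(g, c(1, 1))
  expect_equal(f$distance_km, oracle, tolerance = 1e-10)
})

test_that("degenerate grids behave: lone origin, origin on barrier", {
  lat <- 30 + (0:4) * 0.1; lon <- -75 + (0:4) * 0.1
  land <- matrix(TRUE, 5, 5); land[3, 3] <- FALSE
  g <- shelf_grid(lat, lon, land)
  f <- build_distance_field(g, origin = c(3, 3))
  expect_equal(f$distance_km[3, 3], 0)
  expect_true(all(is.na(f$distance_km[-13])))
  land2 <- matrix(FALSE, 5, 5); land2[1, 1] <- TRUE
  g2 <- shelf_grid(lat, lon, land2)
  expect_error(build_distance_field(g2, origin = c(1, 1)), "barrier")
  # disconnected pockets are unreachable, not an error
  land3 <- matrix(FALSE, 5, 5); land3[, 3] <- TRUE
  g3 <- shelf_grid(lat, lon, land3)
  f3 <- build_distance_field(g3, origin = c(1, 1))
  expect_true(all(is.infinite(f3$distance_km[, 4:5])))
})

test_that("Dijkstra equals the brute-force oracle on random barrier worlds", {
  for (s in 1:30) {
    g <- random_barrier_grid(s)
    f <- build_distance_field(g, origin = c(1, 1))
    expect_equal(f$distance_km, bf_distance(g, c(1, 1)), tolerance = 1e-10)
  }
})

test_that("adding a barrier never decreases any finite distance", {
  g <- random_barrier_grid(101, p_barrier = 0.2)
  f0 <- build_distance_field(g, origin = c(1, 1))
  land2 <- g$land_mask
  open_cells <- which(!land2 & row(land2) + col(land2) > 4)
  withr::with_seed(7, extra <- sample(open_cells, 10))
  land2[extra] <- TRUE
  g2 <- shelf_grid(g$lat, g$lon, land2)
  f2 <- build_distance_field(g2, origin = c(1, 1))
  both <- is.finite(f0$distance_km) & is.finite(f2$distance_km)
  expect_true(all(f2$distance_km[both] >= f0$distance_km[both] - 1e-12))
})

test_that("distances are invariant to raster padding with land", {
  g <- random_barrier_grid(55)
  f <- build_distance_field(g, origin = c(1, 1))
  nr <- length(g$lat); nc <- length(g$lon)
  dlat <- mean(diff(g$lat)); dlon <- mean(diff(g$lon))
  lat_p <- c(g$lat[1] - dlat, g$lat, g$lat[nr] + dlat)
  lon_p <- c(g$lon[1] - dlon, g$lon, g$lon[nc] + dlon)
  land_p <- matrix(TRUE, nr + 2, nc + 2)
  land_p[2:(nr + 1), 2:(nc + 1)] <- g$land_mask
  gp <- shelf_grid(lat_p, lon_p, land_p)
  # pin the identical metric (padding shifts the mean latitude slightly)
  gp$dx_km <- c(g$dx_km[1], g$dx_km, g$dx_km[nr])
  gp$dy_km <- g$dy_km
  fp <- build_distance_field(gp, origin = c(2, 2))
  expect_equal(fp$distance_km[2:(nr + 1), 2:(nc + 1)], f$distance_km,
               tolerance = 1e-10)
})

test_that("records snap to the nearest traversable cell within snap_km", {
  w <- tiny_world()
  g <- synthetic_shelf_grid(w)
  f <- build_distance_field(g, origin = w$origin)
  # exactly on a sea cell center
  r1 <- tibble::tibble(latitude = g$lat[11], longitude = g$lon[w$coast_col])
  out1 <- poleward_distance(r1, f)
  expect_equal(out1$poleward_distance_km, f$distance_km[11, w$coast_col])
  # one cell inland of the coast: snaps to the coastal sea cell
  r2 <- tibble::tibble(latitude = g$lat[11], longitude = g$lon[w$coast_col - 1])
  out2 <- poleward_distance(r2, f, snap_km = 15)
  expect_equal(out2$poleward_distance_km, f$distance_km[11, w$coast_col])
  # far outside the snapping tolerance: flagged, distance absent
  r3 <- tibble::tibble(latitude = g$lat[11], longitude = g$lon[1] - 5)
  out3 <- poleward_distance(r3, f, snap_km = 25)
  expect_true(is.na(out3$poleward_distance_km))
  expect_match(out3$qc_flags, "unsnappable")
})

test_that("generated distances round-trip through the distance field", {
  w <- tiny_world(n_rows = 120)
  g <- synthetic_shelf_grid(w)
  f <- build_distance_field(g, origin = w$origin)
  sp <- species_sim_spec("rt", 8, 300, 150, 400)
  r <- gen_strandings(sp, w, seed = 21)
  out <- poleward_distance(r, f)
  expect_equal(nrow(out), 10000)
  err <- abs(out$poleward_distance_km - out$placed_distance_km)
  expect_true(all(is.finite(err)))
  expect_lte(max(err), 1.5 * w$cell_km)
})
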