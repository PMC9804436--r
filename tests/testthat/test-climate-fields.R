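# uniform planar cube helpers: build in exact km coordinates
planar_cube <- function(nr = 20, nc = 20, T = 5, gy = 0, gx = 0, gt = 0,
                        noise = 0, seed = 1, base = 10) {
  y_km <- (seq_len(nr) - 1) * 10
  x_km <- (seq_len(nc) - 1) * 10
  arr <- array(NA_real_, c(nr, nc, T))
  withr::with_seed(seed, {
    for (t in seq_len(T)) {
      arr[, , t] <- base + outer(gy * y_km, gx * x_km, "+") + gt * (t - 1) +
        if (noise > 0) matrix(rnorm(nr * nc, 0, noise), nr, nc) else 0
    }
  })
  sst_cube(arr, lat = 30 + (seq_len(nr) - 1) * 0.1,
           lon = -75 + (seq_len(nc) - 1) * 0.1,
           years = 2000 + seq_len(T), dx_km = 10, dy_km = 10)
}

test_that("temporal gradient recovers exact linear warming and flat fields", {
  expect_equal(unique(as.vector(temporal_gradient(planar_cube(gt = 0.05)))),
               0.05, tolerance = 1e-12)
  expect_equal(max(abs(temporal_gradient(planar_cube(gt = 0)))), 0,
               tolerance = 1e-12)
})

test_that("temporal gradient equals a closed-form OLS oracle cell by cell", {
  cube <- planar_cube(nr = 8, nc = 8, T = 12, gt = 0.03, noise = 0.5, seed = 4)
  g <- temporal_gradient(cube)
  for (r in c(1, 4, 8)) for (c in c(2, 5, 7)) {
    expect_equal(g[r, c],
                 ols_slope_oracle(as.numeric(cube$years), cube$data[r, c, ]),
                 tolerance = 1e-10)
  }
})

test_that("cells with too few years are masked", {
  cube <- planar_cube(nr = 5, nc = 5, T = 5, gt = 0.1)
  cube$data[2, 2, 2:5] <- NA   # one usable year only
  cube$data[3, 3, ] <- NA
  g <- temporal_gradient(cube)
  expect_true(is.na(g[2, 2]))
  expect_true(is.na(g[3, 3]))
  expect_equal(g[1, 1], 0.1, tolerance = 1e-12)
})

test_that("spatial gradient matches planar closed forms", {
  g1 <- spatial_gradient(planar_cube(gy = 0.01))
  interior <- g1$magnitude[2:19, 2:19]
  expect_equal(unique(round(as.vector(interior), 12)), 0.01)
  # 3-4-5 triangle: 0.003 N-S with 0.004 E-W gives 0.005
  g2 <- spatial_gradient(planar_cube(gy = 0.003, gx = 0.004))
  expect_equal(unique(round(as.vector(g2$magnitude[2:19, 2:19]), 12)), 0.005)
  # uniform field: zero gradient, velocity masked by the floor
  g3 <- spatial_gradient(planar_cube())
  expect_equal(max(abs(g3$magnitude[2:19, 2:19])), 0)
  v <- climate_velocity(temporal_gradient(planar_cube(gt = 0.05)), g3$magnitude)
  expect_true(all(is.na(v$velocity[2:19, 2:19])))
})

test_that("velocity is the signed gradient ratio and scales linearly", {
  gt <- matrix(0.05, 4, 4); sg <- matrix(0.01, 4, 4)
  v <- climate_velocity(gt, sg)
  expect_equal(unique(as.vector(v$velocity)), 5)
  vneg <- climate_velocity(-gt, sg)
  expect_true(all(vneg$velocity < 0))
  v2 <- climate_velocity(2 * gt, sg)
  expect_equal(v2$velocity, 2 * v$velocity)
  expect_error(climate_velocity(gt, matrix(0.01, 3, 3)), "shape")
})

test_that("regional summaries are order statistics over valid cells", {
  f <- matrix(5, 3, 3)
  expect_equal(unlist(regional_summary(f)[1, 1:3]),
               c(median = 5, q25 = 5, q75 = 5))
  f2 <- matrix(as.numeric(1:100), 10, 10)
  expect_equal(regional_summary(f2)$median, 50.5)
  f3 <- f2; f3[1:50] <- NA
  expect_equal(regional_summary(f3)$n_cells, 50)
  expect_equal(regional_summary(f3)$median, stats::median(51:100))
  expect_error(regional_summary(matrix(NA_real_, 2, 2)), "no valid cells")
})

test_that("anomaly series centers on the baseline and recovers the trend", {
  w <- world_spec(n_rows = 40, n_cols = 20, land_cols = 4, shelf_cols = 12)
  cube <- gen_sst_cube(w, temporal_gradient = 0.062, spatial_gradient = 0.01,
                       noise_sd = 0.1, seed = 8)
  res <- sst_anomaly_series(cube)
  expect_equal(sum(res$series$anomaly), 0, tolerance = 1e-9)
  expect_equal(res$trend$slope, 0.062, tolerance = 0.01)
})

test_that("under a flat climate the anomaly-trend CI covers zero at ~95%", {
  w <- world_spec(n_rows = 15, n_cols = 12, land_cols = 3, shelf_cols = 6)
  covered <- vapply(1:60, function(s) {
    cube <- gen_sst_cube(w, temporal_gradient = 0, spatial_gradient = 0.01,
                         noise_sd = 0.3, seed = s)
    ser <- sst_anomaly_series(cube)$series
    fit <- stats::lm(anomaly ~ year, data = ser)
    ci <- stats::confint(fit)["year", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("area weighting changes summaries only when cell areas differ", {
  f <- matrix(as.numeric(1:16), 4, 4)
  w_equal <- matrix(1, 4, 4)
  expect_equal(regional_summary(f, area_weights = w_equal)$median,
               regional_summary(f, area_weights = 2 * w_equal)$median)
  w_diff <- matrix(rep(c(1, 1, 1, 10), each = 4), 4, 4, byrow = FALSE)
  expect_false(isTRUE(all.equal(
    regional_summary(f)$median,
    regional_summary(f, area_weights = t(w_diff))$median)))
})
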