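fake_records <- function(year, dist) {
  tibble::tibble(year = year, poleward_distance_km = dist)
}

test_that("annual statistics follow the stated definitions", {
  r <- fake_records(rep(2000L, 3), c(100, 200, 300))
  expect_equal(annual_statistic(r, "mean")$value, 200)
  # interpolated order statistic, (n-1)p rule: q05 of 10,20,...,1000 is 59.5
  r2 <- fake_records(rep(2001L, 100), seq(10, 1000, by = 10))
  expect_equal(annual_statistic(r2, "q05")$value, 59.5)
  # degenerate single value
  expect_equal(annual_statistic(fake_records(2000L, 77), "q05")$value, 77)
  expect_error(annual_statistic(fake_records(2000L, NA_real_)), "no records")
})

test_that("annual mean never falls below the annual 5th percentile", {
  for (s in 1:20) {
    withr::with_seed(s, {
      yr <- sample(1996:2020, 300, replace = TRUE)
      d <- rnorm(300, 800, 300)
    })
    r <- fake_records(yr, d)
    m <- annual_statistic(r, "mean")
    q <- annual_statistic(r, "q05")
    expect_true(all(m$value >= q$value))
  }
})

test_that("fit_trend matches the closed-form OLS oracle", {
  ser <- tibble::tibble(year = 1996:2020, value = 100 + 14 * (1996:2020 - 1995))
  fit <- fit_trend(ser)
  expect_equal(fit$slope, 14, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  for (s in 1:10) {
    withr::with_seed(s, df <- tibble::tibble(year = 1996:2015,
                                             value = rnorm(20, 500, 100)))
    expect_equal(fit_trend(df)$slope,
                 ols_slope_oracle(df$year, df$value), tolerance = 1e-10)
  }
  expect_error(fit_trend(tibble::tibble(year = 1:2, value = 1:2)), "at least 3")
})

test_that("slope p-values are uniform under a permutation null", {
  withr::with_seed(99, {
    base <- tibble::tibble(year = 1996:2020, value = rnorm(25, 1000, 200))
    pvals <- vapply(1:500, function(i) {
      fit_trend(tibble::tibble(year = base$year,
                               value = sample(base$value)))$p_value
    }, numeric(1))
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("bootstrap on noiseless linear data collapses to zero width", {
  yr <- rep(1996:2020, each = 4)
  r <- fake_records(yr, 100 + 10 * (yr - 1995))
  bs <- bootstrap_ci(r, "mean", B = 200, seed = 1)
  expect_equal(bs$ci_low, 10, tolerance = 1e-9)
  expect_equal(bs$ci_high, 10, tolerance = 1e-9)
  expect_equal(bs$B, 200)
  expect_warning(bootstrap_ci(r, "mean", B = 50, seed = 1), "unstable")
})

test_that("resamples with fewer than 3 distinct years are redrawn", {
  # 3 years, 2 events each: collapse to <3 years is common, must be redrawn
  r <- fake_records(rep(2000:2002, each = 2), c(1, 2, 11, 12, 21, 22))
  bs <- bootstrap_ci(r, "mean", B = 300, seed = 5)
  expect_gt(bs$n_redraws, 0)
  expect_length(bs$slopes, 300)
  expect_true(all(is.finite(bs$slopes)))
})

test_that("Dunn-Sidak adjustment has its closed form and monotonicity", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.05, 9), 1 - 0.95^(1 / 9), tolerance = 1e-12)
  expect_equal(sidak_adjust(0.05, 9), 0.005683, tolerance = 1e-4)
  a <- vapply(1:20, function(m) sidak_adjust(0.05, m), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_error(sidak_adjust(0.05, 0), "positive integer")
  expect_error(sidak_adjust(1.2, 3), "alpha")
})

test_that("composition series normalizes and recovers a constructed mix", {
  # cool fraction falls linearly 0.8 -> 0.2 over 25 years: slope -0.025/yr
  T_ <- 25
  rows <- lapply(seq_len(T_), function(t) {
    frac <- 0.8 - 0.6 * (t - 1) / (T_ - 1)
    n_cool <- round(200 * frac)
    tibble::tibble(
      species_id = c(rep("harbor_porpoise", n_cool),
                     rep("common_dolphin", 200 - n_cool)),
      year = 1995L + t)
  })
  recs <- dplyr::bind_rows(rows)
  comp <- composition_series(recs)
  sums <- tapply(comp$series$proportion, comp$series$year, sum)
  expect_equal(as.numeric(sums), rep(1, T_))
  cool_slope <- comp$trends_year$slope[comp$trends_year$category == "cool"]
  warm_slope <- comp$trends_year$slope[comp$trends_year$category == "warm"]
  expect_equal(cool_slope, -0.025, tolerance = 0.002)
  expect_equal(warm_slope, 0.025, tolerance = 0.002)
  expect_error(composition_series(
    tibble::tibble(species_id = "mystery_whale", year = 2000L)),
    "mystery_whale")
})

test_that("species proportion trends respect symmetry and degeneracy", {
  one <- tibble::tibble(species_id = "awsd", year = rep(1996:2005, each = 3))
  res <- species_proportion_trend(one, "awsd")
  expect_true(all(res$series$proportion == 1))
  expect_equal(res$trend_year$slope, 0, tolerance = 1e-12)
  # two species swapping shares get equal and opposite slopes
  T_ <- 20
  swap <- dplyr::bind_rows(lapply(seq_len(T_), function(t) {
    n_a <- 5 + t
    tibble::tibble(species_id = c(rep("a", n_a), rep("b", 31 - n_a)),
                   year = 1995L + t)
  }))
  sa <- species_proportion_trend(swap, "a")$trend_year$slope
  sb <- species_proportion_trend(swap, "b")$trend_year$slope
  expect_equal(sa, -sb, tolerance = 1e-12)
})

test_that("convergence check measures the center/trailing-edge gap", {
  ser <- tibble::tibble(year = 2000:2010, value = 100 + (0:10), n = 1L,
                        statistic = "mean")
  same <- convergence_check(ser, ser)
  expect_true(all(same$gaps$gap_km == 0))
  expect_true(same$converged)
  center <- tibble::tibble(year = 2000:2010, value = 1000 + 5 * (0:10))
  trailing <- tibble::tibble(year = 2000:2010, value = 200 + 40 * (0:10))
  cv <- convergence_check(center, trailing)
  expect_true(all(diff(cv$gaps$gap_km) < 0))
  expect_error(convergence_check(center,
                                 tibble::tibble(year = 1980:1985, value = 1)),
               "share no years")
})

test_that("gap is non-negative when center and edge use the same records", {
  withr::with_seed(31, {
    r <- fake_records(sample(1996:2020, 500, replace = TRUE),
                      rnorm(500, 900, 250))
  })
  cv <- convergence_check(annual_statistic(r, "mean"),
                          annual_statistic(r, "q05"))
  expect_true(all(cv$gaps$gap_km >= 0))
})

test_that("edge-censoring diagnostic counts the terminal band", {
  r <- fake_records(rep(2000L, 10), c(rep(100, 7), rep(960, 3)))
  expect_equal(edge_censoring_diagnostic(r, domain_max_km = 1000), 0.3)
  expect_true(is.na(edge_censoring_diagnostic(
    fake_records(2000L, NA_real_), 1000)))
})

test_that("family-wise error stays at alpha under the Sidak adjustment", {
  m <- 5; families <- 400; T_ <- 25
  a_adj <- sidak_adjust(0.05, m)
  withr::with_seed(123, {
    any_sig <- vapply(seq_len(families), function(i) {
      p <- vapply(seq_len(m), function(j) {
        fit_trend(tibble::tibble(year = 1996:2020,
                                 value = rnorm(T_, 0, 1)))$p_value
      }, numeric(1))
      any(p < a_adj)
    }, logical(1))
  })
  rate <- mean(any_sig)
  se <- sqrt(0.05 * 0.95 / families)
  expect_lte(rate, 0.05 + 3 * se)
})
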