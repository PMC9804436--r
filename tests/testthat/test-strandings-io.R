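make_csv <- function(df) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, p, row.names = FALSE)
  p
}

test_that("valid rows parse; malformed rows go to rejects, none vanish", {
  df <- data.frame(
    species_id = c("harbor_porpoise", "awsd", "", "lfpw", "bottlenose"),
    date = c("2001-05-01", "2010-08-13", "2005-01-01", "not-a-date", "1999-02-02"),
    latitude = c("41.5", "40.1", "39.0", "38.5", "36.2"),
    longitude = c("-70.2", "-71.0", "-72.0", "-73.0", "-75.0"))
  out <- read_level_a(make_csv(df))
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$rejects), 2)
  expect_setequal(out$rejects$reject_reason, c("blank_species", "bad_date"))
  expect_equal(nrow(out$records) + nrow(out$rejects), nrow(df))
  expect_error(read_level_a(make_csv(df[, 1:2])), "mandatory")
  expect_error(read_level_a("/nonexistent/file.csv"), "cannot read")
})

test_that("coordinate notations DD, DDM and DMS normalize correctly", {
  recs <- tibble::tibble(
    lat_raw = c("41.5083", "4130.50", "41 30 30 N", "41 75 00 N", "garbage"),
    lon_raw = c("-71.25", "07115.00", "71 15 00 W", "71 15 00 W", "-71"),
    qc_flags = "")
  out <- normalize_coordinates(recs)
  expect_equal(out$latitude[1], 41.5083)
  expect_equal(out$longitude[1], -71.25)
  expect_equal(out$notation[1], "DD")
  expect_equal(out$latitude[2], 41 + 30.5 / 60, tolerance = 1e-9)
  expect_equal(out$longitude[2], -(71 + 15 / 60), tolerance = 1e-9)
  expect_equal(out$notation[2], "DDM")
  expect_equal(out$latitude[3], 41 + 30 / 60 + 30 / 3600, tolerance = 1e-9)
  expect_equal(out$longitude[3], -(71 + 15 / 60), tolerance = 1e-9)
  expect_equal(out$notation[3], "DMS")
  # minutes >= 60 and unparseable tokens flag, never crash
  expect_match(out$qc_flags[4], "coord_unparseable")
  expect_match(out$qc_flags[5], "coord_unparseable")
  expect_true(all(is.na(out$latitude[4:5])))
})

test_that("normalization is idempotent on decimal-degree records", {
  recs <- tibble::tibble(lat_raw = c("41.5", "35.25"),
                         lon_raw = c("-70.123456", "-75.5"), qc_flags = "")
  once <- normalize_coordinates(recs)
  again <- normalize_coordinates(
    tibble::tibble(lat_raw = as.character(once$latitude),
                   lon_raw = as.character(once$longitude), qc_flags = ""))
  expect_equal(again$latitude, once$latitude)
  expect_equal(again$longitude, once$longitude)
  expect_true(all(again$notation == "DD"))
})

test_that("gazetteer cross-check flags match a brute-force distance oracle", {
  gaz <- tibble::tibble(county = sprintf("c%02d", 1:10),
                        latitude = seq(30, 39, by = 1),
                        longitude = rep(-75, 10))
  set.seed(42)
  n <- 50
  recs <- tibble::tibble(
    county = sample(c(gaz$county, "unknown_county"), n, replace = TRUE),
    latitude = runif(n, 29.5, 39.5),
    longitude = runif(n, -76, -74),
    qc_flags = "")
  out <- validate_locations(recs, gaz, max_km = 50)
  idx <- match(recs$county, gaz$county)
  oracle_flag <- ifelse(
    is.na(idx), "no_gazetteer",
    ifelse(haversine_oracle(recs$longitude, recs$latitude,
                            gaz$longitude[idx], gaz$latitude[idx]) > 50,
           "location_mismatch", ""))
  expect_equal(out$qc_flags, oracle_flag)
})

test_that("coordinates at the county centroid raise no flags; distant ones do", {
  gaz <- tibble::tibble(county = "a", latitude = 40, longitude = -72)
  ok <- validate_locations(
    tibble::tibble(county = "a", latitude = 40, longitude = -72, qc_flags = ""),
    gaz, max_km = 50)
  expect_equal(ok$qc_flags, "")
  far <- validate_locations(
    tibble::tibble(county = "a", latitude = 44.5, longitude = -72, qc_flags = ""),
    gaz, max_km = 50)
  expect_match(far$qc_flags, "location_mismatch")
})

test_that("region assignment splits at Cape Hatteras, closed to the north", {
  recs <- tibble::tibble(latitude = c(42, 30, 35.25, NA))
  out <- assign_region(recs)
  expect_equal(out$region, c("NEUS", "SEUS", "NEUS", "out_of_scope"))
  mix <- tibble::tibble(latitude = c(runif(60, 36, 44), runif(40, 26, 34)))
  expect_equal(sum(assign_region(mix)$region == "NEUS"), 60)
  expect_equal(sum(assign_region(mix)$region == "SEUS"), 40)
})

test_that("five-per-year rule reproduces the nine-species inclusion list", {
  prof <- species_profiles()
  counts <- stats::setNames(prof$mean_annual_n, prof$species_id)
  counts <- counts[!duplicated(names(counts))]
  counts <- c(counts, beluga = 0.2, killer_whale = 1.5)
  elig <- eligible_species(counts)
  expect_setequal(elig, c("harbor_porpoise", "awsd", "lfpw", "bottlenose",
                          "common_dolphin", "striped_dolphin",
                          "rissos_dolphin", "pygmy_sperm", "dwarf_sperm"))
  expect_length(elig, 9)
})

test_that("registry restricts categories and trailing-edge species", {
  reg <- species_registry()
  expect_true(all(reg$climatic_category %in% climatic_categories()))
  expect_setequal(reg$species_id[reg$trailing_edge],
                  c("harbor_porpoise", "lfpw", "awsd"))
})
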