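#' Read Level-A-style stranding records from CSV
#'
#' Parses a CSV of stranding events, keeping coordinates as raw strings for
#' [normalize_coordinates()]. Rows are never silently dropped: rows missing
#' a species or a usable date are routed to a rejects table with a reason
#' code, and `nrow(input) == nrow(records) + nrow(rejects)` always holds.
#'
#' @param path CSV file with a header.
#' @param col_map named list mapping the roles `species`, `date`, `lat`,
#'   `lon` (mandatory) and optionally `state`, `county`, `description`,
#'   `event_id` to column names in the file.
#' @return list with tibbles `records` (columns `event_id`, `species_id`,
#'   `year`, `date`, `lat_raw`, `lon_raw`, `state`, `county`, `description`,
#'   `qc_flags`) and `rejects` (the offending raw rows plus `reject_reason`).
#' @export
read_level_a <- function(path,
                         col_map = list(species = "species_id", date = "date",
                                        lat = "latitude", lon = "longitude",
                                        state = "state", county = "county",
                                        description = "description",
                                        event_id = "event_id")) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  mandatory <- c("species", "date", "lat", "lon")
  for (role in mandatory) {
    cl <- col_map[[role]]
    if (is.null(cl) || !cl %in% names(raw)) {
      stop("input is missing mandatory column for role '", role, "'",
           call. = FALSE)
    }
  }
  get_col <- function(role) {
    cl <- col_map[[role]]
    if (!is.null(cl) && cl %in% names(raw)) raw[[cl]] else rep(NA_character_, nrow(raw))
  }
  species <- trimws(get_col("species"))
  date_s <- trimws(get_col("date"))
  year <- suppressWarnings(as.integer(substr(date_s, 1, 4)))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(species) | species == ""] <- "blank_species"
  bad_year <- is.na(reason) & (is.na(year) | year < 1800 | year > 2100)
  reason[bad_year] <- "bad_date"
  keep <- is.na(reason)
  ev <- get_col("event_id")
  ev[is.na(ev) | ev == ""] <- sprintf("row_%05d", which(is.na(ev) | ev == ""))
  records <- tibble::tibble(
    event_id = ev[keep],
    species_id = species[keep],
    year = year[keep],
    date = date_s[keep],
    lat_raw = get_col("lat")[keep],
    lon_raw = get_col("lon")[keep],
    state = get_col("state")[keep],
    county = get_col("county")[keep],
    description = get_col("description")[keep],
    qc_flags = ""
  )
  rejects <- tibble::as_tibble(raw[!keep, , drop = FALSE])
  rejects$reject_reason <- reason[!keep]
  list(records = records, rejects = rejects)
}

#' Normalize coordinate notation to decimal degrees
#'
#' Stranding databases mix three coordinate notations: plain decimal degrees
#' (DD), degrees with decimal minutes packed into one number (DDM, e.g.
#' `4130.50` = 41 deg 30.5 min), and sexagesimal degrees-minutes-seconds
#' (DMS, e.g. `41 30 30 N`). The notation is inferred per token: explicit
#' hemisphere letters or space-separated groups mean DMS/DDM; a single
#' number too large for its axis (or matching the packed `ddmm.m` pattern)
#' means DDM; anything else is DD, so normalizing an already-DD value is the
#' identity. Western longitudes inside the study bounding box are forced
#' negative. Unparseable tokens and minutes or seconds >= 60 set the
#' `coord_unparseable` flag instead of raising.
#'
#' @param records tibble from [read_level_a()] (uses `lat_raw`, `lon_raw`),
#'   or any data frame with those columns.
#' @param lon_bbox longitudes (negative west) within which a positive
#'   longitude is interpreted as a west value with the sign dropped.
#' @return `records` with `latitude`, `longitude` (decimal degrees),
#'   `notation` (`"DD"`, `"DDM"`, `"DMS"`, or `NA`), and updated `qc_flags`.
#' @export
normalize_coordinates <- function(records, lon_bbox = c(-100, -50)) {
  lat_p <- parse_coord_vec_(records$lat_raw, axis = "lat")
  lon_p <- parse_coord_vec_(records$lon_raw, axis = "lon")
  lon_val <- lon_p$value
  force_w <- !is.na(lon_val) & lon_val > 0 &
    -lon_val >= lon_bbox[1] & -lon_val <= lon_bbox[2]
  lon_val[force_w] <- -lon_val[force_w]
  bad <- is.na(lat_p$value) | is.na(lon_val) |
    abs(lat_p$value) > 90 | abs(lon_val) > 180
  flags <- if ("qc_flags" %in% names(records)) records$qc_flags else rep("", nrow(records))
  flags[bad] <- vapply(flags[bad], add_flag_, character(1), new = "coord_unparseable")
  notation <- ifelse(is.na(lat_p$notation), lon_p$notation, lat_p$notation)
  records$latitude <- ifelse(bad, NA_real_, lat_p$value)
  records$longitude <- ifelse(bad, NA_real_, lon_val)
  records$notation <- ifelse(bad, NA_character_, notation)
  records$qc_flags <- flags
  records
}

# parse one coordinate string; returns value (signed) and notation
#' @noRd
parse_coord_one_ <- function(s, axis) {
  fail <- list(value = NA_real_, notation = NA_character_)
  if (is.na(s)) return(fail)
  s <- trimws(s)
  if (s == "") return(fail)
  sign <- 1
  hem <- regmatches(s, regexpr("[NSEWnsew]", s))
  if (length(hem) == 1) {
    if (toupper(hem) %in% c("S", "W")) sign <- -1
    s <- trimws(gsub("[NSEWnsew]", "", s))
  }
  # unicode degree/minute/second marks and symbols act as separators
  s <- gsub("[°'\"′″]", " ", s)
  s <- gsub(",", " ", s)
  if (grepl("^-", s)) { sign <- sign * -1; s <- sub("^-", "", s) }
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  if (length(nums) == 0 || any(is.na(nums)) || any(nums < 0)) return(fail)
  if (length(nums) == 3) {
    if (nums[2] >= 60 || nums[3] >= 60) return(fail)
    return(list(value = sign * (nums[1] + nums[2] / 60 + nums[3] / 3600),
                notation = "DMS"))
  }
  if (length(nums) == 2) {
    if (nums[2] >= 60) return(fail)
    return(list(value = sign * (nums[1] + nums[2] / 60), notation = "DMS"))
  }
  v <- nums[1]
  max_deg <- if (axis == "lat") 90 else 180
  int_digits <- nchar(sub("\\..*$", "", sprintf("%.0f", floor(v))))
  ddm_digits <- if (axis == "lat") 3 else 4   # ddmm.m / dddmm.m packing
  if (v > max_deg || int_digits > ddm_digits) {
    deg <- floor(v / 100)
    minutes <- v - deg * 100
    if (minutes >= 60 || deg > max_deg) return(fail)
    return(list(value = sign * (deg + minutes / 60), notation = "DDM"))
  }
  list(value = sign * v, notation = "DD")
}

#' @noRd
parse_coord_vec_ <- function(x, axis) {
  res <- lapply(as.character(x), parse_coord_one_, axis = axis)
  list(value = vapply(res, `[[`, numeric(1), "value"),
       notation = vapply(res, `[[`, character(1), "notation"))
}

#' Cross-check stranding locations against a county gazetteer
#'
#' Records whose coordinates lie more than `max_km` (great-circle) from the
#' centroid of their recorded county are flagged `location_mismatch`;
#' counties absent from the gazetteer yield `no_gazetteer` (never an error).
#' When a [shelf_grid()] is supplied, coordinates farther than `inland_km`
#' from any traversable sea cell are flagged `inland`.
#'
#' @param records data frame with `county`, `latitude`, `longitude`,
#'   `qc_flags`.
#' @param gazetteer data frame `county`, `latitude`, `longitude`.
#' @param max_km mismatch threshold; default 50 km (county scale).
#' @param grid optional [shelf_grid()] for the inland check.
#' @param inland_km tolerance for the inland check; default 25 km.
#' @return `records` with updated `qc_flags`.
#' @export
validate_locations <- function(records, gazetteer, max_km = 50,
                               grid = NULL, inland_km = 25) {
  idx <- match(records$county, gazetteer$county)
  flags <- records$qc_flags
  for (i in seq_len(nrow(records))) {
    if (is.na(records$latitude[i]) || is.na(records$longitude[i])) next
    if (is.na(idx[i])) {
      flags[i] <- add_flag_(flags[i], "no_gazetteer")
    } else {
      d <- gc_distance_km(records$longitude[i], records$latitude[i],
                          gazetteer$longitude[idx[i]], gazetteer$latitude[idx[i]])
      if (d > max_km) flags[i] <- add_flag_(flags[i], "location_mismatch")
    }
  }
  if (!is.null(grid)) {
    cells <- which(grid$traversable, arr.ind = TRUE)
    clat <- grid$lat[cells[, 1]]; clon <- grid$lon[cells[, 2]]
    for (i in seq_len(nrow(records))) {
      if (is.na(records$latitude[i]) || is.na(records$longitude[i])) next
      d <- min(gc_distance_km(records$longitude[i], records$latitude[i],
                              clon, clat))
      if (d > inland_km) flags[i] <- add_flag_(flags[i], "inland")
    }
  }
  records$qc_flags <- flags
  records
}

#' Assign NEUS/SEUS region by latitude
#'
#' Splits records at Cape Hatteras into the Northeast (NEUS) and Southeast
#' (SEUS) United States shelf regions. The split is closed to the north: a
#' record exactly on the split latitude is NEUS. Records without usable
#' coordinates become `out_of_scope`.
#'
#' @param records data frame with `latitude`.
#' @param split_latitude boundary, decimal degrees N; default 35.25 (Cape
#'   Hatteras).
#' @return `records` with a `region` column.
#' @export
assign_region <- function(records, split_latitude = 35.25) {
  records$region <- dplyr::case_when(
    is.na(records$latitude) ~ "out_of_scope",
    records$latitude >= split_latitude ~ "NEUS",
    TRUE ~ "SEUS"
  )
  records
}
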