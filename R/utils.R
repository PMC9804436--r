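# km per degree of latitude (spherical Earth, R = 6371 km); degree-longitude
# spacing is this scaled by cos(latitude)
KM_PER_DEG <- 111.32

#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance in kilometres; thin wrapper around
#' [geosphere::distHaversine()] so every module measures geographic distance
#' the same way.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectors recycle).
#' @return distance in km.
#' @export
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}
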