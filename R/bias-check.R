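#' Observer-effort bias regression
#'
#' Human observers must be present for a stranding to enter the record, so a
#' spatial trend in coastal population growth that mirrors the poleward
#' shifts would confound them. This regresses county percent population
#' change (2000 to 2020, as a percent of the 2000 population) on the
#' poleward distance of the county centroid, optionally restricted to the
#' distance window over which a particular species' shift was observed.
#'
#' @param census table with `poleward_distance_km` and `pct_change` (see
#'   [gen_census()]); centroids are snapped to the distance field like
#'   strandings before calling this.
#' @param window optional `c(min_km, max_km)` distance window.
#' @return a [fit_trend()] of `pct_change` on `poleward_distance_km`.
#' @export
bias_regression <- function(census, window = NULL) {
  df <- census
  if (!is.null(window)) {
    df <- df[df$poleward_distance_km >= window[1] &
               df$poleward_distance_km <= window[2], ]
  }
  if (nrow(df) < 3) {
    stop("fewer than 3 counties in the distance window", call. = FALSE)
  }
  fit_trend(df, response = "pct_change", predictor = "poleward_distance_km")
}

#' Bias check across the full coast and per-species windows
#'
#' Runs [bias_regression()] for the whole coastline and for each supplied
#' species window, applies a Dunn-Sidak adjustment across the family of
#' regressions, and states, per species, whether the census trend runs in
#' the direction that could mimic the observed poleward shift (population
#' growth increasing with poleward distance) or opposes it.
#'
#' @param census as in [bias_regression()].
#' @param species_windows named list of `c(min_km, max_km)` windows, one per
#'   species showing a shift.
#' @param alpha family-wise error rate; default 0.05.
#' @return tibble: `scope`, `slope`, `p_value`, `n`, `alpha_adjusted`,
#'   `significant`, `confound_direction` (TRUE when a significant positive
#'   slope could mimic a poleward shift).
#' @export
bias_report <- function(census, species_windows = list(), alpha = 0.05) {
  m <- 1L + length(species_windows)
  a_adj <- sidak_adjust(alpha, m)
  one <- function(scope, window) {
    fit <- bias_regression(census, window)
    tibble::tibble(scope = scope, slope = fit$slope, p_value = fit$p_value,
                   n = fit$n, alpha_adjusted = a_adj,
                   significant = fit$p_value < a_adj,
                   confound_direction = fit$p_value < a_adj & fit$slope > 0)
  }
  out <- one("full_coast", NULL)
  for (sp in names(species_windows)) {
    out <- dplyr::bind_rows(out, one(sp, species_windows[[sp]]))
  }
  out
}
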