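#' Annual statistic of poleward distance
#'
#' Collapses one species' events to an annual series: the mean poleward
#' distance (center of distribution) or the 5th percentile (trailing edge).
#' Percentiles use linear interpolation between order statistics (R's type
#' 7, the `(n - 1) p` rule), so the q05 of a single value is that value.
#' Years with no events are absent from the series, not imputed; events
#' without an assigned distance are ignored.
#'
#' @param records data frame with `year` and `poleward_distance_km`.
#' @param statistic `"mean"` or `"q05"`.
#' @param prob percentile for `"q05"`; default 0.05.
#' @return tibble `year`, `value`, `n`, `statistic`.
#' @export
annual_statistic <- function(records, statistic = c("mean", "q05"),
                             prob = 0.05) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("year", "poleward_distance_km") %in% names(records)))
  ok <- !is.na(records$poleward_distance_km) & !is.na(records$year)
  if (!any(ok)) stop("no records with assigned poleward distance", call. = FALSE)
  d <- records$poleward_distance_km[ok]
  yr <- records$year[ok]
  f <- if (statistic == "mean") {
    mean
  } else {
    function(v) stats::quantile(v, prob, names = FALSE, type = 7)
  }
  agg <- tapply(d, yr, f)
  n <- tapply(d, yr, length)
  tibble::tibble(year = as.integer(names(agg)), value = as.numeric(agg),
                 n = as.integer(n), statistic = statistic)
}

#' Event-level bootstrap CI for a shift slope
#'
#' Resamples event rows with replacement (each resample the size of the
#' original data, conserving the distance-year pairing of each row), then
#' recomputes the annual statistic and its OLS slope on year. The 95%
#' interval is the 0.025/0.975 quantiles of the `B` bootstrap slopes. A
#' resample landing on fewer than 3 distinct years cannot support a trend
#' and is redrawn; redraws are counted and reported.
#'
#' @param records data frame with `year` and `poleward_distance_km`.
#' @param statistic `"mean"` or `"q05"`.
#' @param B bootstrap replicates; default 1000 (warns below 100).
#' @param seed integer seed.
#' @param level confidence level; default 0.95.
#' @return list: `ci_low`, `ci_high`, `slopes` (length `B`), `n_redraws`,
#'   `B`.
#' @export
bootstrap_ci <- function(records, statistic = c("mean", "q05"), B = 1000,
                         seed = NULL, level = 0.95) {
  statistic <- match.arg(statistic)
  if (B < 100) warning("B < 100 gives unstable quantile estimates")
  ok <- !is.na(records$poleward_distance_km) & !is.na(records$year)
  d <- records$poleward_distance_km[ok]
  yr <- as.numeric(records$year[ok])
  N <- length(d)
  if (N < 3) stop("too few events to bootstrap", call. = FALSE)
  qfun <- function(v) stats::quantile(v, 0.05, names = FALSE, type = 7)
  with_seed_(seed, {
    slopes <- numeric(B)
    n_redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(N, N, replace = TRUE)
        yy <- yr[idx]
        if (length(unique(yy)) >= 3L) break
        n_redraws <- n_redraws + 1L
      }
      dd <- d[idx]
      stat <- if (statistic == "mean") {
        rowsum(dd, yy) / tabulate(match(yy, sort(unique(yy))))
      } else {
        as.matrix(tapply(dd, yy, qfun))
      }
      x <- as.numeric(rownames(stat))
      y <- as.numeric(stat)
      mx <- mean(x); my <- mean(y)
      slopes[b] <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
    }
    a <- (1 - level) / 2
    ci <- stats::quantile(slopes, c(a, 1 - a), names = FALSE, type = 7)
    list(ci_low = ci[1], ci_high = ci[2], slopes = slopes,
         n_redraws = n_redraws, B = B)
  })
}

#' Full shift fit for one species
#'
#' Convenience wrapper: annual statistic, OLS trend, event-level bootstrap
#' CI, folded into one `trend_fit`.
#'
#' @inheritParams bootstrap_ci
#' @param alpha_adjusted family-wise-adjusted alpha to record on the fit.
#' @return a [fit_trend()] object with bootstrap fields filled in.
#' @export
fit_shift <- function(records, statistic = c("mean", "q05"), B = 1000,
                      seed = NULL, alpha_adjusted = NA_real_) {
  statistic <- match.arg(statistic)
  series <- annual_statistic(records, statistic)
  fit <- fit_trend(series)
  bs <- bootstrap_ci(records, statistic, B = B, seed = seed)
  fit$boot_ci_low <- bs$ci_low
  fit$boot_ci_high <- bs$ci_high
  fit$n_boot <- bs$B
  fit$alpha_adjusted <- alpha_adjusted
  fit
}

#' Dunn-Sidak adjusted significance level
#'
#' `alpha' = 1 - (1 - alpha)^(1/m)` controls the family-wise Type I error
#' rate at `alpha` across `m` independent comparisons.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return adjusted per-test alpha.
#' @examples
#' sidak_adjust(0.05, 9)  # 0.005683...
#' @export
sidak_adjust <- function(alpha, m) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  1 - (1 - alpha)^(1 / m)
}

#' Climatic-category composition of strandings through time
#'
#' Per-year proportion of stranding events in each climatic category (warm,
#' cool, arctic, cosmopolitan), with the denominator being all events in the
#' region-year, plus OLS trends of each category's proportion on year and
#' (optionally) on the regional SST anomaly.
#'
#' @param records data frame with `species_id`, `year` (and `region` if
#'   `region` is given).
#' @param registry [species_registry()]-shaped table.
#' @param region optional region filter (`"NEUS"`/`"SEUS"`).
#' @param anomaly optional anomaly series (tibble `year`, `anomaly`) for
#'   trends against SST anomaly.
#' @return list: `series` (tibble `year`, `category`, `n`, `total`,
#'   `proportion`), `trends_year` and (if anomaly given) `trends_anomaly`,
#'   both tibbles with one row per category.
#' @export
composition_series <- function(records, registry = species_registry(),
                               region = NULL, anomaly = NULL) {
  if (!is.null(region)) records <- records[records$region %in% region, ]
  cat_of <- stats::setNames(registry$climatic_category, registry$species_id)
  unmapped <- setdiff(unique(records$species_id), names(cat_of))
  if (length(unmapped) > 0) {
    stop("species not in registry: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  records$category <- unname(cat_of[records$species_id])
  cats <- climatic_categories()
  series <- records |>
    dplyr::count(.data$year, .data$category) |>
    tidyr::complete(year = unique(records$year),
                    category = cats, fill = list(n = 0L)) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(total = sum(.data$n),
                  proportion = .data$n / .data$total) |>
    dplyr::ungroup()
  trend_for <- function(cat, response, pred_df, predictor) {
    s <- series[series$category == cat, ]
    s <- dplyr::inner_join(s, pred_df, by = "year")
    fit <- fit_trend(s, response = "proportion", predictor = predictor)
    tibble::tibble(category = cat, slope = fit$slope, p_value = fit$p_value,
                   r_squared = fit$r_squared, n = fit$n)
  }
  year_df <- tibble::tibble(year = sort(unique(series$year)))
  trends_year <- dplyr::bind_rows(lapply(cats, trend_for, response = "proportion",
                                         pred_df = year_df, predictor = "year"))
  out <- list(series = series, trends_year = trends_year)
  if (!is.null(anomaly)) {
    out$trends_anomaly <- dplyr::bind_rows(
      lapply(cats, trend_for, response = "proportion",
             pred_df = anomaly[, c("year", "anomaly")], predictor = "anomaly"))
  }
  out
}

#' Relative-abundance trend for one species
#'
#' The species' share of all stranding events per region-year, regressed on
#' year and (optionally) on SST anomaly.
#'
#' @inheritParams composition_series
#' @param species species_id to track.
#' @return list: `series` (tibble `year`, `n`, `total`, `proportion`),
#'   `trend_year`, and `trend_anomaly` when an anomaly series is supplied.
#' @export
species_proportion_trend <- function(records, species, region = NULL,
                                     anomaly = NULL) {
  if (!is.null(region)) records <- records[records$region %in% region, ]
  series <- records |>
    dplyr::count(.data$year, name = "total") |>
    dplyr::left_join(
      records |>
        dplyr::filter(.data$species_id == species) |>
        dplyr::count(.data$year),
      by = "year") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  proportion = .data$n / .data$total)
  out <- list(series = series,
              trend_year = fit_trend(series, response = "proportion"))
  if (!is.null(anomaly)) {
    s <- dplyr::inner_join(series, anomaly[, c("year", "anomaly")], by = "year")
    out$trend_anomaly <- fit_trend(s, response = "proportion",
                                   predictor = "anomaly")
  }
  out
}

#' Center / trailing-edge convergence check
#'
#' The yearly gap between the center of distribution (annual mean) and the
#' trailing edge (annual 5th percentile). When the gap shrinks below
#' `threshold_km` within the last `last_k` observed years, the two series
#' have (nearly) converged -- the signature of a distribution pressing
#' against the poleward end of the sampled domain.
#'
#' @param center,trailing annual series from [annual_statistic()].
#' @param last_k window (years with data, counted from the most recent) for
#'   the convergence flag; default 5.
#' @param threshold_km gap threshold, km; default 50.
#' @return list: `gaps` (tibble `year`, `center`, `trailing`, `gap_km`),
#'   `converged` flag, `min_recent_gap_km`.
#' @export
convergence_check <- function(center, trailing, last_k = 5,
                              threshold_km = 50) {
  gaps <- dplyr::inner_join(
    dplyr::select(center, "year", center = "value"),
    dplyr::select(trailing, "year", trailing = "value"),
    by = "year")
  if (nrow(gaps) == 0) stop("series share no years", call. = FALSE)
  gaps$gap_km <- gaps$center - gaps$trailing
  recent <- utils::tail(gaps[order(gaps$year), ], last_k)
  min_gap <- min(recent$gap_km)
  list(gaps = gaps, converged = min_gap < threshold_km,
       min_recent_gap_km = min_gap)
}

#' Domain-edge censoring diagnostic
#'
#' Share of a species' events falling in the terminal fraction of the
#' along-shelf domain. When distribution mass piles up at the poleward end
#' of the sampled coastline, the annual mean understates the true center of
#' distribution; this diagnostic quantifies how much of the record sits in
#' that terminal band.
#'
#' @param records data frame with `poleward_distance_km`.
#' @param domain_max_km poleward extent of the sampled domain, km.
#' @param terminal_frac terminal band width as a fraction of the domain;
#'   default 0.10.
#' @return proportion of events with distance beyond
#'   `(1 - terminal_frac) * domain_max_km`.
#' @export
edge_censoring_diagnostic <- function(records, domain_max_km,
                                      terminal_frac = 0.10) {
  d <- records$poleward_distance_km
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  mean(d > (1 - terminal_frac) * domain_max_km)
}
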