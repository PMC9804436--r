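#' Ordinary least-squares trend with optional bootstrap interval
#'
#' A `trend_fit` bundles the OLS slope of an annual statistic against a
#' predictor (almost always calendar year) with the quantities the shift
#' analyses report alongside it: intercept, two-sided slope p-value, r-squared,
#' the 2.5%/97.5% bootstrap quantiles of the slope when a bootstrap has been
#' run, and the Dunn-Sidak-adjusted alpha used to judge significance within a
#' family of tests.
#'
#' @param series data frame with at least the predictor and response columns.
#' @param response,predictor column names (strings). Defaults fit the annual
#'   statistic (`value`) on `year`.
#' @return object of class `trend_fit`: a list with elements `slope`,
#'   `intercept`, `p_value`, `r_squared`, `n`, `boot_ci_low`, `boot_ci_high`,
#'   `n_boot`, `alpha_adjusted`, `response`, `predictor`.
#' @examples
#' fit_trend(data.frame(year = 1:10, value = 3 + 14 * (1:10)))
#' @export
fit_trend <- function(series, response = "value", predictor = "year") {
  stopifnot(is.data.frame(series))
  if (!all(c(response, predictor) %in% names(series))) {
    stop("`series` must contain columns '", response, "' and '", predictor, "'",
         call. = FALSE)
  }
  x <- series[[predictor]]
  y <- series[[response]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("trend fit needs at least 3 observations (got ", length(x), ")",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # degenerate noiseless fixtures trip summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  p <- if (nrow(co) >= 2L) co[2L, 4L] else NA_real_
  new_trend_fit(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    p_value = unname(p),
    r_squared = sm$r.squared,
    n = length(x),
    response = response,
    predictor = predictor
  )
}

#' @noRd
new_trend_fit <- function(slope, intercept, p_value, r_squared, n,
                          boot_ci_low = NA_real_, boot_ci_high = NA_real_,
                          n_boot = NA_integer_, alpha_adjusted = NA_real_,
                          response = "value", predictor = "year") {
  structure(
    list(slope = slope, intercept = intercept, p_value = p_value,
         r_squared = r_squared, n = n,
         boot_ci_low = boot_ci_low, boot_ci_high = boot_ci_high,
         n_boot = n_boot, alpha_adjusted = alpha_adjusted,
         response = response, predictor = predictor),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Trend fit: %s ~ %s (n = %d)\n", x$response, x$predictor, x$n))
  cat(sprintf("  slope %.4g  intercept %.4g  p = %.3g  r2 = %.3f\n",
              x$slope, x$intercept, x$p_value, x$r_squared))
  if (is.finite(x$boot_ci_low)) {
    cat(sprintf("  bootstrap 95%% CI [%.4g, %.4g]  (B = %d)\n",
                x$boot_ci_low, x$boot_ci_high, x$n_boot))
  }
  if (is.finite(x$alpha_adjusted)) {
    cat(sprintf("  Dunn-Sidak adjusted alpha = %.4g\n", x$alpha_adjusted))
  }
  invisible(x)
}

#' @export
as.data.frame.trend_fit <- function(x, ...) {
  data.frame(slope = x$slope, intercept = x$intercept, p_value = x$p_value,
             r_squared = x$r_squared, n = x$n,
             boot_ci_low = x$boot_ci_low, boot_ci_high = x$boot_ci_high,
             n_boot = x$n_boot, alpha_adjusted = x$alpha_adjusted)
}
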