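# Hydrology: flow-exceedance statistics from gauge records, area rating
# curves fitted by non-linear least squares, and total stream power.

#' Flow exceedance value of a daily record
#'
#' The discharge exceeded `percent_exceeded`% of days, i.e. the
#' (100 - p)th percentile of the flow distribution. Percentiles use linear
#' interpolation between order statistics (the default sample-quantile
#' definition, `stats::quantile` type 7).
#' @param flows numeric vector of daily mean flows (m^3/s).
#' @param percent_exceeded exceedance level in percent (2 = high flow,
#'   80 = low flow).
#' @param min_days minimum record length (default 30); shorter records error.
#' @param warn_days records shorter than this raise a warning (default 365).
#' @return discharge in m^3/s.
#' @export
flow_exceedance <- function(flows, percent_exceeded, min_days = 30, warn_days = 365) {
  flows <- flows[!is.na(flows)]
  if (length(flows) < min_days)
    stop("flow record too short: ", length(flows),
         " days (need at least ", min_days, ")")
  if (length(flows) < warn_days)
    warning("flow record shorter than a year (", length(flows), " days)")
  if (any(flows < 0)) stop("negative flows in record")
  unname(stats::quantile(flows, probs = 1 - percent_exceeded / 100, type = 7))
}

#' Fit a discharge-area rating curve
#'
#' Non-linear least squares fit of Q = a * Area^b across gauges at one
#' exceedance level, started from the log-log linear estimate.
#' @param areas_km2 gauge contributing areas (km^2).
#' @param q gauge discharges at the exceedance level (m^3/s).
#' @param level label ("Q2" or "Q80"), carried in the result.
#' @return object of class `rating_curve`: list(a, b, level, rss, n).
#' @export
fit_rating_curve <- function(areas_km2, q, level = "Q") {
  ok <- is.finite(areas_km2) & is.finite(q)
  areas_km2 <- areas_km2[ok]; q <- q[ok]
  if (length(areas_km2) < 2L)
    stop("insufficient data: rating curves need at least 2 gauges")
  if (length(unique(round(areas_km2, 10))) < 2L)
    stop("rating curve unidentifiable: all gauge areas equal")
  if (any(q <= 0)) stop("non-positive discharge in rating data")
  st <- stats::lm(log(q) ~ log(areas_km2))
  start <- list(a = exp(unname(stats::coef(st)[1])), b = unname(stats::coef(st)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(q ~ a * areas_km2^b, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("rating-curve fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), level = level,
                 rss = sum(stats::residuals(fit)^2), n = length(q)),
            class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  cat(sprintf("Rating curve %s: Q = %.6g * Area^%.6g  (n = %d gauges, RSS = %.3g)\n",
              x$level, x$a, x$b, x$n, x$rss))
  invisible(x)
}

#' Predict reach discharge from a rating curve
#' @param curve a `rating_curve`.
#' @param area_km2 contributing areas (km^2).
#' @return discharge in m^3/s.
#' @export
reach_discharge <- function(curve, area_km2) {
  stopifnot(inherits(curve, "rating_curve"))
  curve$a * area_km2^curve$b
}

#' Total stream power
#'
#' Omega = rho * g * Q * S with rho = 1000 kg/m^3 and g = 9.8 m/s^2.
#' @param q discharge (m^3/s).
#' @param slope dimensionless channel slope (must be non-negative).
#' @return stream power in watts.
#' @export
stream_power <- function(q, slope) {
  if (any(slope < 0, na.rm = TRUE)) stop("negative slope")
  if (any(q < 0, na.rm = TRUE)) stop("negative discharge")
  1000 * 9.8 * q * slope
}

#' Fit Q2 and Q80 rating curves from gauge records
#'
#' Convenience wrapper: computes per-gauge exceedance flows and fits both
#' rating curves, pooling all gauges.
#' @param flows data.frame with columns `flow_m3s`, `gauge_id`.
#' @param gauges data.frame with columns `gauge_id`, `area_km2`.
#' @return list with elements `q2` and `q80`, each a `rating_curve`.
#' @export
fit_gauge_ratings <- function(flows, gauges) {
  if (nrow(gauges) < 2L)
    stop("insufficient data: rating curves need at least 2 gauges")
  qx <- function(p) vapply(gauges$gauge_id, function(g)
    flow_exceedance(flows$flow_m3s[flows$gauge_id == g], p, warn_days = 0),
    numeric(1))
  list(q2 = fit_rating_curve(gauges$area_km2, qx(2), "Q2"),
       q80 = fit_rating_curve(gauges$area_km2, qx(80), "Q80"))
}
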