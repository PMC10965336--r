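# Cumulative-threshold phenology metrics and the seasonal body-mass smooth.
#
# The phenology of a daily series is summarised by the real-valued
# day-of-year at which the linearly interpolated cumulative curve first
# reaches a threshold fraction (0.5 by default: the "median date"). The
# convention is that day d's value counts fully toward the cumulative at d,
# and interpolation runs between consecutive sampled cumulative points; when
# a sampled cumulative hits the threshold exactly, that day is returned
# (first crossing), which makes the metric deterministic on flat stretches.

#' Cumulative fraction curve of a daily series
#'
#' @param doy Sampled days (ascending).
#' @param value Nonnegative daily values; `NA` days are treated as unsampled
#'   and dropped.
#' @return data.frame (doy, cum_fraction) with a nondecreasing fraction
#'   ending at exactly 1. If the season total is zero the fractions are `NA`
#'   and the attribute `defined` is `FALSE`.
#' @export
cumulative_curve <- function(doy, value) {
  stopifnot(length(doy) == length(value))
  ok <- !is.na(value)
  doy <- doy[ok]; value <- value[ok]
  if (is.unsorted(doy, strictly = TRUE)) {
    o <- order(doy)
    doy <- doy[o]; value <- value[o]
  }
  if (any(value < 0)) stop("daily values must be nonnegative")
  total <- sum(value)
  if (length(value) == 0L || total <= 0) {
    out <- data.frame(doy = doy, cum_fraction = rep(NA_real_, length(doy)))
    attr(out, "defined") <- FALSE
    return(out)
  }
  cf <- cumsum(value) / total
  cf[length(cf)] <- 1  # guard against accumulated rounding at the endpoint
  out <- data.frame(doy = doy, cum_fraction = cf)
  attr(out, "defined") <- TRUE
  out
}

#' Threshold (median) date of a daily series
#'
#' Real-valued day at which the linearly interpolated cumulative fraction
#' first reaches `threshold` (0.5 = median date). Undefined (NA) for an
#' all-zero series.
#'
#' @inheritParams cumulative_curve
#' @param threshold Cumulative fraction in (0, 1), default 0.5.
#' @return Numeric day-of-year, or `NA` if the series total is zero.
#' @export
median_date <- function(doy, value, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  cc <- cumulative_curve(doy, value)
  if (!attr(cc, "defined")) return(NA_real_)
  .first_crossing(cc$doy, cc$cum_fraction, threshold)
}

#' Phenology estimates per year and currency
#'
#' Applies [median_date()] to each (year, currency) slice of a stacked
#' daily-series table.
#'
#' @param daily_series data.frame (year, currency, doy, value, ...) as
#'   produced by [reconstruct_daily_series()].
#' @param threshold Cumulative fraction, default 0.5.
#' @return data.frame (year, currency, median_doy, total, defined); `total`
#'   is the seasonal sum of the daily values (specimens or mg per trap-day)
#'   and years with zero total are flagged `defined = FALSE`.
#' @export
phenology_estimates <- function(daily_series, threshold = 0.5) {
  .check_columns(daily_series, c("year", "currency", "doy", "value"),
                 "daily series")
  keys <- unique(daily_series[c("year", "currency")])
  keys <- keys[order(keys$currency, keys$year), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    s <- daily_series[daily_series$year == keys$year[i] &
                        daily_series$currency == keys$currency[i], ]
    total <- sum(s$value, na.rm = TRUE)
    md <- median_date(s$doy, s$value, threshold)
    data.frame(year = keys$year[i], currency = keys$currency[i],
               median_doy = md, total = total, defined = !is.na(md),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Seasonal smooth of per-specimen body mass
#'
#' Penalized cubic-regression-spline smooth (GCV-selected smoothness) of
#' specimen mass against day-of-year, fitted on the log scale by default
#' because specimen masses span orders of magnitude. Fitted values and
#' approximate 95% pointwise intervals are returned on the response (mg)
#' scale over the integer-day range of the data.
#'
#' @param doy Day-of-year of each specimen.
#' @param mass_mg Specimen masses (mg, > 0 when `log_scale`).
#' @param basis_dim Spline basis dimension (default 10); reduced with a
#'   warning when the data have fewer distinct days.
#' @param log_scale Model log(mass) (default `TRUE`).
#' @return List with `grid` (data.frame doy, fit, lower, upper), the fitted
#'   `model` (a [mgcv::gam()] object) and `basis_dim` actually used.
#' @export
seasonal_bodymass_smooth <- function(doy, mass_mg, basis_dim = 10L,
                                     log_scale = TRUE) {
  stopifnot(length(doy) == length(mass_mg))
  ok <- is.finite(doy) & is.finite(mass_mg)
  doy <- doy[ok]; mass_mg <- mass_mg[ok]
  if (log_scale && any(mass_mg <= 0)) stop("masses must be > 0 on the log scale")
  if (length(doy) < basis_dim + 2L) {
    stop("too few observations for the requested basis dimension")
  }
  k <- basis_dim
  n_days <- length(unique(doy))
  if (n_days < k) {
    warning("fewer distinct days (", n_days, ") than basis functions; ",
            "reducing basis dimension to ", n_days)
    k <- n_days
  }
  y <- if (log_scale) log(mass_mg) else mass_mg
  dat <- data.frame(doy = doy, y = y)
  model <- mgcv::gam(y ~ s(doy, bs = "cr", k = k), data = dat,
                     method = "GCV.Cp")
  grid_doy <- seq(floor(min(doy)), ceiling(max(doy)))
  pred <- mgcv::predict.gam(model, newdata = data.frame(doy = grid_doy),
                            se.fit = TRUE)
  fit <- pred$fit
  lo <- fit - 1.96 * pred$se.fit
  hi <- fit + 1.96 * pred$se.fit
  if (log_scale) {
    fit <- exp(fit); lo <- exp(lo); hi <- exp(hi)
  }
  list(grid = data.frame(doy = grid_doy, fit = as.numeric(fit),
                         lower = as.numeric(lo), upper = as.numeric(hi)),
       model = model, basis_dim = k)
}
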