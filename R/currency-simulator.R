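# Conceptual currency simulator.
#
# A year's resource phenology is a parametric abundance distribution
# (Gaussian or skew-normal) over day-of-year. Biomass is obtained by
# multiplying the abundance curve pointwise with a "weight line": a linear
# relationship between mean mass per specimen and date. Because the weight
# line rises through the season, the biomass curve's 50%-cumulative date
# falls after the abundance curve's. Advancing the abundance distribution
# by a fixed number of days per year while varying the weight line's slope
# across years yields three regimes: constant slope (equal rates of change
# in both currencies), steepening slope (biomass peak advances more slowly
# than abundance), flattening slope (biomass peak advances faster).

#' Parametric abundance phenology
#'
#' @param family `"gaussian"` or `"skew_normal"`.
#' @param location_doy Location parameter (the Gaussian mean; for the
#'   skew-normal, the location parameter xi, not the mean).
#' @param scale_days Scale parameter in days (> 0).
#' @param shape Skewness parameter alpha; must be 0 for the Gaussian family
#'   (a skew-normal with shape 0 reduces exactly to the Gaussian).
#' @param total_abundance Season total number of specimens.
#' @return Object of class `abundance_shape`.
#' @export
abundance_shape <- function(family = c("gaussian", "skew_normal"),
                            location_doy = 180, scale_days = 10,
                            shape = 0, total_abundance = 1000) {
  family <- match.arg(family)
  if (scale_days <= 0) stop("scale_days must be > 0")
  if (family == "gaussian" && shape != 0) {
    stop("the gaussian family has shape = 0; use family = 'skew_normal'")
  }
  stopifnot(total_abundance > 0)
  structure(list(family = family, location_doy = as.numeric(location_doy),
                 scale_days = as.numeric(scale_days), shape = as.numeric(shape),
                 total_abundance = as.numeric(total_abundance)),
            class = "abundance_shape")
}

# skew-normal density: (2/omega) phi(z) Phi(alpha z), z = (x - xi)/omega
dskewnorm <- function(x, location, scale, shape) {
  z <- (x - location) / scale
  2 / scale * stats::dnorm(z) * stats::pnorm(shape * z)
}

#' Evaluate an abundance distribution on a day grid
#'
#' @param shape An [abundance_shape()].
#' @param day_grid Numeric grid of days; must cover at least
#'   location +/- 5 scale units, otherwise the support is truncated and an
#'   error is raised.
#' @return Daily abundance values (density x total abundance) on the grid.
#' @export
evaluate_abundance <- function(shape, day_grid) {
  stopifnot(inherits(shape, "abundance_shape"))
  lo <- shape$location_doy - 5 * shape$scale_days
  hi <- shape$location_doy + 5 * shape$scale_days
  if (min(day_grid) > lo || max(day_grid) < hi) {
    stop("day grid truncates the distribution's support; ",
         "cover at least location +/- 5 scale units")
  }
  dens <- if (shape$family == "gaussian") {
    stats::dnorm(day_grid, shape$location_doy, shape$scale_days)
  } else {
    dskewnorm(day_grid, shape$location_doy, shape$scale_days, shape$shape)
  }
  shape$total_abundance * dens
}

#' Mean and standard deviation of an abundance shape
#'
#' For the skew-normal, mean = xi + omega delta sqrt(2/pi) and
#' variance = omega^2 (1 - 2 delta^2 / pi) with
#' delta = alpha / sqrt(1 + alpha^2).
#'
#' @param shape An [abundance_shape()].
#' @return Named numeric vector `c(mean, sd)` in days.
#' @export
shape_moments <- function(shape) {
  stopifnot(inherits(shape, "abundance_shape"))
  if (shape$family == "gaussian" || shape$shape == 0) {
    return(c(mean = shape$location_doy, sd = shape$scale_days))
  }
  delta <- shape$shape / sqrt(1 + shape$shape^2)
  c(mean = shape$location_doy + shape$scale_days * delta * sqrt(2 / pi),
    sd = shape$scale_days * sqrt(1 - 2 * delta^2 / pi))
}

#' Moment-matched symmetric counterpart of a skewed shape
#'
#' The Gaussian with the same mean, standard deviation and season total as
#' the given (skew-normal) shape. This is the fair symmetric reference when
#' asking what skewness per se does to currency-specific phenology: at equal
#' location and scale parameters a skew-normal has a smaller SD than the
#' Gaussian, which would confound the comparison.
#'
#' @param shape An [abundance_shape()].
#' @return A gaussian `abundance_shape`.
#' @export
matched_gaussian <- function(shape) {
  m <- shape_moments(shape)
  abundance_shape("gaussian", m[["mean"]], m[["sd"]],
                  total_abundance = shape$total_abundance)
}

#' Weight line: mean mass per specimen as a linear function of date
#'
#' @param intercept_mg Mean specimen mass (mg) at the reference day (> 0).
#' @param slope_mg_per_day Change in mean specimen mass per day.
#' @param reference_doy Day at which the intercept applies.
#' @param year Optional year label.
#' @return Object of class `weight_line`.
#' @export
weight_line <- function(intercept_mg, slope_mg_per_day,
                        reference_doy = 120, year = NA_integer_) {
  if (intercept_mg <= 0) stop("intercept_mg must be > 0")
  structure(list(intercept_mg = as.numeric(intercept_mg),
                 slope_mg_per_day = as.numeric(slope_mg_per_day),
                 reference_doy = as.numeric(reference_doy),
                 year = year),
            class = "weight_line")
}

#' Biomass curve from an abundance curve and a weight line
#'
#' Pointwise product of daily abundance with the weight line. A weight that
#' is not strictly positive anywhere on the grid is an error (clipping would
#' silently distort the distribution's tail).
#'
#' @param abundance_values Daily abundance on `day_grid`
#'   (from [evaluate_abundance()]).
#' @param wl A [weight_line()].
#' @param day_grid The day grid the abundance was evaluated on.
#' @return Daily biomass values (mg per day) on the grid.
#' @export
biomass_from_abundance <- function(abundance_values, wl, day_grid) {
  stopifnot(inherits(wl, "weight_line"),
            length(abundance_values) == length(day_grid))
  w <- wl$intercept_mg + wl$slope_mg_per_day * (day_grid - wl$reference_doy)
  if (any(w <= 0)) {
    stop("weight line is nonpositive on part of the evaluation grid ",
         "(minimum ", format(min(w)), " mg)")
  }
  abundance_values * w
}

#' Scenario specification for the multi-year simulation
#'
#' Default slope schedules give the three canonical regimes: I, constant
#' slope; II, slope doubling each year (steepening); III, the reverse
#' (flattening). All slopes must be positive, reflecting the general
#' positive relationship between body size and development time.
#'
#' @param label `"I"`, `"II"`, `"III"` or `"custom"`.
#' @param n_years Number of simulated years (default 5).
#' @param advance_days_per_year Fixed annual advance of the abundance
#'   distribution (default 2 d/yr).
#' @param base_shape An [abundance_shape()] for year 1.
#' @param weight_slopes Per-year weight-line slopes (mg/day); defaults by
#'   label, required for `"custom"`.
#' @param weight_intercept_mg,weight_reference_doy Weight-line anchor shared
#'   by all years.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(label = c("I", "II", "III", "custom"),
                          n_years = 5L, advance_days_per_year = 2,
                          base_shape = abundance_shape("gaussian", 180, 10),
                          weight_slopes = NULL,
                          weight_intercept_mg = 1,
                          weight_reference_doy = 120) {
  label <- match.arg(label)
  stopifnot(.is_count(n_years), inherits(base_shape, "abundance_shape"))
  if (is.null(weight_slopes)) {
    weight_slopes <- switch(label,
      I = rep(0.02, n_years),
      II = 0.005 * 2^(seq_len(n_years) - 1L),
      III = rev(0.005 * 2^(seq_len(n_years) - 1L)),
      custom = stop("custom scenarios require explicit weight_slopes"))
  }
  if (length(weight_slopes) != n_years) {
    stop("weight_slopes must have one value per year")
  }
  if (any(weight_slopes < 0)) stop("weight slopes must be nonnegative")
  if (label %in% c("II", "III") && any(weight_slopes <= 0)) {
    stop("Scenario ", label, " considers positive slopes only")
  }
  d <- diff(weight_slopes)
  if (label == "I" && any(d != 0)) stop("Scenario I requires equal slopes")
  if (label == "II" && any(d <= 0)) {
    stop("Scenario II requires strictly increasing slopes")
  }
  if (label == "III" && any(d >= 0)) {
    stop("Scenario III requires strictly decreasing slopes")
  }
  structure(list(label = label, n_years = as.integer(n_years),
                 advance_days_per_year = as.numeric(advance_days_per_year),
                 base_shape = base_shape,
                 weight_slopes = as.numeric(weight_slopes),
                 weight_intercept_mg = as.numeric(weight_intercept_mg),
                 weight_reference_doy = as.numeric(weight_reference_doy)),
            class = "scenario_spec")
}

#' Run a multi-year currency scenario
#'
#' For each year the base abundance distribution is advanced by
#' advance x (year - 1) days and multiplied by that year's weight line; the
#' 50%-cumulative date of each currency is computed by linear interpolation
#' on the evaluation grid (step `grid_step` over location +/- 6 scale units)
#' and the per-currency rate of phenological change is the OLS slope of
#' date on year.
#'
#' @param spec A [scenario_spec()].
#' @param grid_step Grid resolution in days (default 0.01).
#' @return Object of class `scenario_result`: list with `per_year`
#'   (year, weight_slope, abundance_date, biomass_date, gap_days),
#'   `rate_abundance`, `rate_biomass` (d/yr) and `rate_difference`
#'   (biomass - abundance).
#' @export
run_scenario <- function(spec, grid_step = 0.01) {
  stopifnot(inherits(spec, "scenario_spec"))
  base <- spec$base_shape
  per_year <- do.call(rbind, lapply(seq_len(spec$n_years), function(y) {
    loc <- base$location_doy - spec$advance_days_per_year * (y - 1L)
    shp <- abundance_shape(base$family, loc, base$scale_days, base$shape,
                           base$total_abundance)
    grid <- seq(loc - 6 * base$scale_days, loc + 6 * base$scale_days,
                by = grid_step)
    ab <- evaluate_abundance(shp, grid)
    wl <- weight_line(spec$weight_intercept_mg, spec$weight_slopes[y],
                      spec$weight_reference_doy, year = y)
    bm <- biomass_from_abundance(ab, wl, grid)
    data.frame(year = y, weight_slope = spec$weight_slopes[y],
               abundance_date = median_date(grid, ab),
               biomass_date = median_date(grid, bm))
  }))
  per_year$gap_days <- per_year$biomass_date - per_year$abundance_date
  rate <- function(dates) {
    unname(ols_trend(per_year$year, dates)["slope"])
  }
  structure(list(per_year = per_year,
                 rate_abundance = rate(per_year$abundance_date),
                 rate_biomass = rate(per_year$biomass_date),
                 rate_difference = rate(per_year$biomass_date) -
                   rate(per_year$abundance_date),
                 label = spec$label),
            class = "scenario_result")
}

#' Compare currency-specific rates of phenological change
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param tol Equality tolerance in d/yr (default 0.05).
#' @return List with `rate_difference` (biomass - abundance, d/yr) and
#'   `classification`: `"equal within tol"`, `"biomass slower"` (the biomass
#'   peak advances more slowly than abundance) or `"biomass faster"`.
#' @export
compare_rates <- function(result, tol = 0.05) {
  stopifnot(inherits(result, "scenario_result"))
  d <- result$rate_difference
  cls <- if (abs(d) < tol) "equal within tol" else
    if (d > 0) "biomass slower" else "biomass faster"
  list(rate_difference = d, classification = cls)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Currency scenario ", x$label, " (", nrow(x$per_year), " years)\n", sep = "")
  print(x$per_year, row.names = FALSE, digits = 6)
  cat(sprintf("rate of change: abundance %.4f, biomass %.4f d/yr (difference %+.4f)\n",
              x$rate_abundance, x$rate_biomass, x$rate_difference))
  invisible(x)
}
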