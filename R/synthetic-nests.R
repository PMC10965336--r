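# Synthetic shorebird nest records and chick growth measurements.

#' Specification of synthetic nest hatch dates
#'
#' @param mean_hatch_doy_year0 Mean hatch day-of-year in the first year.
#' @param hatch_trend_days_per_year Linear change in mean hatch DOY per year
#'   (negative = advancing).
#' @param hatch_sd_days Between-nest SD of hatch dates within a year (> 0).
#' @param nests_per_year Number of nests per year (>= 1).
#' @return Object of class `nest_spec`.
#' @export
nest_spec <- function(mean_hatch_doy_year0 = 181,
                      hatch_trend_days_per_year = 0,
                      hatch_sd_days = 4,
                      nests_per_year = 20L) {
  if (!is.numeric(hatch_sd_days) || hatch_sd_days <= 0) {
    stop("hatch_sd_days must be > 0")
  }
  if (!.is_count(nests_per_year)) stop("nests_per_year must be a count >= 1")
  structure(list(mean_hatch_doy_year0 = as.numeric(mean_hatch_doy_year0),
                 hatch_trend_days_per_year = as.numeric(hatch_trend_days_per_year),
                 hatch_sd_days = as.numeric(hatch_sd_days),
                 nests_per_year = as.integer(nests_per_year)),
            class = "nest_spec")
}

#' Generate synthetic nest records
#'
#' Hatch dates per year are Normal(mean + trend x (year - year0), sd),
#' rounded to integer day-of-year (field hatch dates are daily-resolution).
#'
#' @param spec A [nest_spec()].
#' @param years Integer vector of years.
#' @param seed Integer seed.
#' @return data.frame (year, hatch_doy).
#' @export
generate_nest_dataset <- function(spec, years, seed) {
  stopifnot(inherits(spec, "nest_spec"), length(years) >= 1L)
  set.seed(derive_seeds(seed, 1L))
  year0 <- years[1L]
  out <- do.call(rbind, lapply(years, function(yr) {
    mu <- spec$mean_hatch_doy_year0 +
      spec$hatch_trend_days_per_year * (yr - year0)
    data.frame(year = yr,
               hatch_doy = as.integer(round(
                 stats::rnorm(spec$nests_per_year, mu, spec$hatch_sd_days))))
  }))
  rownames(out) <- NULL
  out
}

#' Generate synthetic chick growth measurements
#'
#' Masses follow a three-parameter logistic growth curve with additive
#' Gaussian measurement noise, truncated below at a small positive floor
#' (a chick cannot weigh nothing).
#'
#' @param params A [logistic_params()].
#' @param n_chicks Number of chicks.
#' @param ages Vector of measurement ages (days, >= 0) applied to every chick.
#' @param noise_sd Measurement noise SD in grams (>= 0).
#' @param seed Integer seed.
#' @param mass_floor_g Lower truncation bound in grams.
#' @return data.frame (chick_id, age_days, mass_g).
#' @export
generate_chick_growth <- function(params, n_chicks, ages, noise_sd = 0,
                                  seed = 1L, mass_floor_g = 0.1) {
  stopifnot(inherits(params, "logistic_params"), .is_count(n_chicks))
  if (any(ages < 0)) stop("ages must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(derive_seeds(seed, 1L))
  grid <- expand.grid(age_days = as.numeric(ages),
                      chick_id = seq_len(n_chicks),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- logistic_mass(grid$age_days, params)
  mass <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(chick_id = grid$chick_id, age_days = grid$age_days,
             mass_g = pmax(mass, mass_floor_g))
}
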