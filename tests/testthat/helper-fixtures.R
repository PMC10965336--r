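# Shared fixtures, built in code.

# minimal two-taxon community: light taxon early, heavy taxon late
two_taxon_spec <- function(years = 2000:2004, ...) {
  taxa <- list(
    taxon_spec("light_early", "adult", peak_doy = 170, emergence_sd_days = 8,
               mean_daily_catch_at_peak = 5,
               length_distribution(meanlog = log(2), sdlog = 0.2),
               allometric_coefficients("light_early", 0.05, 2.5)),
    taxon_spec("heavy_late", "adult", peak_doy = 190, emergence_sd_days = 8,
               mean_daily_catch_at_peak = 5,
               length_distribution(meanlog = log(6), sdlog = 0.2),
               allometric_coefficients("heavy_late", 0.05, 2.5))
  )
  community_spec(taxa = taxa, years = years, plots = 2L, traps_per_plot = 2L,
                 ...)
}

# single taxon whose specimens all weigh exactly 4 mg (dyadic, so biomass is
# an exact power-of-two multiple of abundance)
unit_mass_spec <- function(years = 2000:2002) {
  taxa <- list(
    taxon_spec("uniform", "adult", peak_doy = 190, emergence_sd_days = 10,
               mean_daily_catch_at_peak = 4,
               length_distribution(lengths_mm = 8),
               allometric_coefficients("uniform", 0.5, 1))
  )
  community_spec(taxa = taxa, years = years, plots = 2L, traps_per_plot = 2L)
}

# random catch table with intervals that may straddle the window
random_catch_table <- function(n = 60L, seed = 1L, window = c(157L, 238L)) {
  set.seed(seed)
  doy_start <- sample(seq(window[1L] - 10L, window[2L] - 2L), n, replace = TRUE)
  len <- sample(3:9, n, replace = TRUE)
  data.frame(year = sample(2000:2002, n, replace = TRUE),
             doy_start = doy_start, doy_end = doy_start + len - 1L,
             plot = sample(1:2, n, replace = TRUE),
             trap = sample(1:2, n, replace = TRUE),
             taxon = sample(c("a", "b"), n, replace = TRUE),
             life_stage = "adult",
             count = rpois(n, 6), stringsAsFactors = FALSE)
}

# random strictly-positive daily series on a contiguous day range
random_daily_series <- function(seed, n_days = 30L, start = 160L) {
  set.seed(seed)
  doy <- start + seq_len(n_days) - 1L
  value <- rgamma(n_days, shape = 1.5, rate = 0.5)
  list(doy = doy, value = value)
}

# independent fine-grid inversion of the interpolated cumulative curve:
# builds the piecewise-linear cumulative on a 0.001-day grid and finds the
# first grid day at/above the threshold
grid_inversion_median <- function(doy, value, threshold = 0.5,
                                  step = 0.001) {
  cf <- cumsum(value) / sum(value)
  grid <- seq(doy[1L], doy[length(doy)], by = step)
  interp <- approx(doy, cf, xout = grid, method = "linear")$y
  grid[which(interp >= threshold)[1L]]
}
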