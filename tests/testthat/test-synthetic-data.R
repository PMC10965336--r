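# Synthetic community, nest and chick generators.

test_that("a zero-rate community yields all-zero counts and undefined truth", {
  taxa <- list(
    taxon_spec("ghost", "adult", peak_doy = 180, emergence_sd_days = 5,
               mean_daily_catch_at_peak = 0,
               length_distribution(lengths_mm = 3),
               allometric_coefficients("ghost", 0.05, 2.5))
  )
  spec <- community_spec(taxa, years = 2000:2001, plots = 1L,
                         traps_per_plot = 1L)
  ds <- generate_trap_dataset(spec, seed = 7)
  expect_true(all(ds$catches$count == 0L))
  expect_false(any(ds$truth$per_year$defined))
  expect_true(all(is.na(ds$truth$per_year$lag_days)))
})

test_that("generation is byte-identical under a fixed spec and seed", {
  spec <- two_taxon_spec()
  a <- generate_trap_dataset(spec, seed = 11)
  b <- generate_trap_dataset(spec, seed = 11)
  expect_identical(a, b)
  c <- generate_trap_dataset(spec, seed = 12)
  expect_false(identical(a$catches$count, c$catches$count))
})

test_that("spec validation rejects degenerate designs", {
  expect_error(community_spec(list(), years = 2000), "at least one taxon")
  taxa <- two_taxon_spec()$taxa
  expect_error(community_spec(taxa, years = 2000, window_start_doy = 200,
                              window_end_doy = 190), "window_start")
  expect_error(community_spec(taxa, years = 2000, window_start_doy = 157,
                              window_end_doy = 160,
                              sampling_interval_days = 7L),
               "shorter than one sampling interval")
  expect_error(taxon_spec("x", "adult", 180, emergence_sd_days = 0,
                          mean_daily_catch_at_peak = 1,
                          length_distribution(lengths_mm = 3),
                          allometric_coefficients("x", 1, 1)),
               "emergence_sd_days")
})

test_that("a late-heavy community has a positive true currency lag, matching
           an independent fine-grid computation", {
  spec <- two_taxon_spec(years = 2000)
  ds <- generate_trap_dataset(spec, seed = 3)
  truth <- ds$truth$per_year
  expect_gt(truth$lag_days[1L], 0)

  # independent oracle: rebuild both weighted medians from first principles
  grid <- seq(157, 238, by = 0.001)
  ab <- bm <- numeric(length(grid))
  for (taxon in spec$taxa) {
    r <- taxon$mean_daily_catch_at_peak *
      exp(-(grid - taxon$peak_doy)^2 / (2 * taxon$emergence_sd_days^2))
    lens <- ds$lengths$length_mm[ds$lengths$taxon == taxon$name]
    m <- mean(taxon$allometry$coeff_a * lens^taxon$allometry$exponent_b)
    ab <- ab + r
    bm <- bm + r * m
  }
  first_at <- function(v) {
    cf <- cumsum(v) / sum(v)
    i <- which(cf >= 0.5)[1L]
    grid[i - 1L] + (0.5 - cf[i - 1L]) / (cf[i] - cf[i - 1L]) * 0.001
  }
  expect_equal(truth$abundance_median_doy[1L], first_at(ab), tolerance = 1e-6)
  expect_equal(truth$biomass_median_doy[1L], first_at(bm), tolerance = 1e-6)
})

test_that("the true lag is zero when all taxa share one peak and one length
           distribution", {
  ld <- length_distribution(lengths_mm = c(3, 4, 5))
  al <- allometric_coefficients("any", 0.05, 2.5)
  taxa <- list(
    taxon_spec("a", "adult", 185, 8, 4, ld, al),
    taxon_spec("b", "adult", 185, 8, 2, ld, al)
  )
  spec <- community_spec(taxa, years = 2000, plots = 1L, traps_per_plot = 1L)
  ds <- generate_trap_dataset(spec, seed = 5)
  expect_lt(abs(ds$truth$per_year$lag_days[1L]), 1e-3)
})

test_that("mean interval counts converge to the integral of the daily rate", {
  # many traps, one taxon: Monte-Carlo mean within 3 standard errors
  taxa <- list(
    taxon_spec("mc", "adult", 190, 8, 3,
               length_distribution(lengths_mm = 3),
               allometric_coefficients("mc", 0.05, 2.5))
  )
  spec <- community_spec(taxa, years = 2000, plots = 10L,
                         traps_per_plot = 20L)
  ds <- generate_trap_dataset(spec, seed = 21)
  first <- ds$catches[ds$catches$doy_start == 157, ]
  expected <- sum(3 * exp(-((157:163) - 190)^2 / (2 * 64)))
  se <- sqrt(expected / nrow(first))  # Poisson
  expect_lt(abs(mean(first$count) - expected), 3 * se)
})

test_that("negative-binomial counts are overdispersed relative to Poisson", {
  taxa <- list(
    taxon_spec("od", "adult", 190, 20, 10,
               length_distribution(lengths_mm = 3),
               allometric_coefficients("od", 0.05, 2.5))
  )
  base <- community_spec(taxa, years = 2000, plots = 10L, traps_per_plot = 20L)
  od <- community_spec(taxa, years = 2000, plots = 10L, traps_per_plot = 20L,
                       nb_dispersion = 1)
  v_pois <- var(generate_trap_dataset(base, seed = 9)$catches$count)
  v_nb <- var(generate_trap_dataset(od, seed = 9)$catches$count)
  expect_gt(v_nb, 2 * v_pois)
})

test_that("nest generation honours mean, trend and determinism", {
  # degenerate sd: all hatch dates collapse to the mean after rounding
  tight <- nest_spec(mean_hatch_doy_year0 = 185, hatch_trend_days_per_year = 0,
                     hatch_sd_days = 1e-9, nests_per_year = 50L)
  nests <- generate_nest_dataset(tight, 2000:2002, seed = 1)
  expect_true(all(nests$hatch_doy == 185L))
  expect_error(nest_spec(hatch_sd_days = 0), "hatch_sd_days")

  # OLS slope of yearly medians recovers the trend
  spec <- nest_spec(mean_hatch_doy_year0 = 185,
                    hatch_trend_days_per_year = 0.5, hatch_sd_days = 4,
                    nests_per_year = 1000L)
  years <- 2000:2014
  nests <- generate_nest_dataset(spec, years, seed = 8)
  med <- hatch_medians(nests)
  tr <- ols_trend(med$year, med$hatch_median_doy)
  expect_lt(abs(tr[["slope"]] - 0.5), 0.1)

  expect_identical(generate_nest_dataset(spec, years, seed = 8),
                   generate_nest_dataset(spec, years, seed = 8))
})

test_that("chick growth generation lies on the logistic curve when noiseless", {
  p <- logistic_params(60, 0.2, 10)
  chicks <- generate_chick_growth(p, n_chicks = 3L, ages = 0:20,
                                  noise_sd = 0, seed = 2)
  expect_equal(chicks$mass_g, logistic_mass(chicks$age_days, p))
  # inflection age gives half the asymptote
  expect_equal(logistic_mass(10, p), 30)
  expect_error(generate_chick_growth(p, 2L, ages = c(-1, 3), 0, 1), "ages")
})
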