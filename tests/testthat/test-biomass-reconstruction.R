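# Interval spreading, length assignment, allometry and daily series.

test_that("interval catches are spread uniformly over trap-days", {
  catches <- data.frame(year = 2000, doy_start = 160L, doy_end = 166L,
                        plot = 1L, trap = 1L, taxon = "a",
                        life_stage = "adult", count = 14L)
  daily <- spread_interval_catches(catches)
  expect_equal(nrow(daily), 7L)
  expect_equal(daily$doy, 160:166)
  expect_equal(daily$count, rep(2, 7L))
})

test_that("window truncation drops the outside days' shares", {
  # 8-day interval with 4 days inside the window: half the count retained
  catches <- data.frame(year = 2000, doy_start = 235L, doy_end = 242L,
                        plot = 1L, trap = 1L, taxon = "a",
                        life_stage = "adult", count = 8L)
  daily <- spread_interval_catches(catches, window = c(157L, 238L))
  expect_equal(daily$doy, 235:238)
  expect_equal(sum(daily$count), 4)

  outside <- data.frame(year = 2000, doy_start = 240L, doy_end = 246L,
                        plot = 1L, trap = 1L, taxon = "a",
                        life_stage = "adult", count = 5L)
  expect_message(res <- spread_interval_catches(outside), "dropped")
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_dropped"), 1L)

  bad <- transform(catches, doy_end = doy_start - 1L)
  expect_error(spread_interval_catches(bad), "doy_end < doy_start")
})

test_that("spreading conserves counts up to the dropped shares", {
  catches <- random_catch_table(n = 80L, seed = 4L)
  daily <- suppressMessages(spread_interval_catches(catches))
  n_days <- catches$doy_end - catches$doy_start + 1L
  inside <- pmax(0L, pmin(catches$doy_end, 238L) -
                   pmax(catches$doy_start, 157L) + 1L)
  retained <- sum(catches$count * inside / n_days)
  expect_equal(sum(daily$count), retained, tolerance = 1e-12)
})

test_that("length assignment is degenerate-safe, seeded, and unbiased", {
  catches <- data.frame(year = 2000, doy_start = 160L, doy_end = 166L,
                        plot = 1L, trap = 1L, taxon = "a",
                        life_stage = "adult", count = 10L)
  single <- data.frame(taxon = "a", life_stage = "adult", length_mm = 3)
  sp <- assign_lengths(catches, single, seed = 1)
  expect_equal(nrow(sp), 10L)
  expect_true(all(sp$length_mm == 3))

  two <- data.frame(taxon = "a", life_stage = c("adult", "adult"),
                    length_mm = c(2, 4))
  expect_identical(assign_lengths(catches, two, seed = 5),
                   assign_lengths(catches, two, seed = 5))

  big <- transform(catches, count = 100000L)
  sp <- assign_lengths(big, two, seed = 9)
  expect_lt(abs(mean(sp$length_mm) - 3), 0.01)

  orphan <- transform(catches, taxon = "mystery")
  expect_error(assign_lengths(orphan, two, seed = 1), "mystery")
})

test_that("power-law allometry evaluates correctly", {
  expect_equal(length_to_mass(5, 1, 1), 5)
  expect_equal(length_to_mass(2, 0.05, 2.6), 0.05 * 2^2.6)
  expect_equal(length_to_mass(2, 0.05, 2.6), 0.3031, tolerance = 1e-3)
  expect_equal(length_to_mass(c(1, 7, 100), 0.3, 0), rep(0.3, 3L))
  expect_error(length_to_mass(-1, 1, 2), "positive")
  expect_error(length_to_mass(2, 0, 2), "coeff_a")
})

test_that("daily series average across active traps and flag unsampled days", {
  activity <- data.frame(year = 2000, doy = 157:238, n_active_traps = 1L)
  one <- data.frame(year = 2000, doy = 160L, value = 2)
  s <- build_daily_series(one, activity, currency = "biomass")
  expect_equal(s$value[s$doy == 160], 2)
  expect_equal(sum(s$value > 0), 1L)

  activity$n_active_traps <- 2L
  s2 <- build_daily_series(one, activity, currency = "biomass")
  expect_equal(s2$value[s2$doy == 160], 1)

  activity$n_active_traps[activity$doy > 230] <- 0L
  s3 <- build_daily_series(one, activity, currency = "abundance")
  expect_true(all(is.na(s3$value[s3$doy > 230])))
  expect_true(all(!is.na(s3$value[s3$doy <= 230])))
})

test_that("reconstruction conserves total count and mass exactly", {
  spec <- two_taxon_spec(years = 2000:2001)
  ds <- generate_trap_dataset(spec, seed = 13)
  daily <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                    mode = "expected")
  em <- expected_specimen_mass(ds$lengths, ds$allometry)
  m <- match(ds$catches$taxon, em$taxon)
  for (yr in 2000:2001) {
    in_year <- ds$catches$year == yr
    for (cur in c("abundance", "biomass")) {
      s <- daily[daily$year == yr & daily$currency == cur, ]
      lhs <- sum(s$value * s$n_active_traps, na.rm = TRUE)
      rhs <- if (cur == "abundance") sum(ds$catches$count[in_year]) else
        sum(ds$catches$count[in_year] * em$mean_mass_mg[m][in_year])
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("abundance is seed-invariant and expectation mode equals the
           seed-average of stochastic mode", {
  spec <- two_taxon_spec(years = 2000)
  ds <- generate_trap_dataset(spec, seed = 17)
  exp_series <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                         mode = "expected")
  s1 <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                 mode = "stochastic", seed = 1)
  s2 <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                 mode = "stochastic", seed = 2)
  ab <- function(s) s$value[s$currency == "abundance"]
  bm <- function(s) s$value[s$currency == "biomass"]
  expect_identical(ab(s1), ab(s2))
  expect_identical(ab(s1), ab(exp_series))
  expect_false(identical(bm(s1), bm(s2)))

  # seed-average of the stochastic biomass converges on the expectation
  n_seeds <- 200L
  acc <- 0
  for (k in seq_len(n_seeds)) {
    sk <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                   mode = "stochastic", seed = 1000 + k)
    acc <- acc + bm(sk)
  }
  avg <- acc / n_seeds
  target <- bm(exp_series)
  keep <- !is.na(target) & target > 0
  # 3-standard-error band on the seasonal total
  per_seed_tot <- numeric(20L)
  for (k in seq_len(20L)) {
    sk <- reconstruct_daily_series(ds$catches, ds$lengths, ds$allometry,
                                   mode = "stochastic", seed = 2000 + k)
    per_seed_tot[k] <- sum(bm(sk)[keep])
  }
  se_tot <- sd(per_seed_tot) / sqrt(n_seeds)
  expect_lt(abs(sum(avg[keep]) - sum(target[keep])), 3 * se_tot)
})
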