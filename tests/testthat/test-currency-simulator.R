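# Parametric abundance shapes, weight lines, and the three scenarios.

test_that("abundance evaluation is symmetric, normalised, and guarded", {
  g <- seq(100, 260, by = 0.01)
  shp <- abundance_shape("gaussian", 180, 10, total_abundance = 500)
  v <- evaluate_abundance(shp, g)
  expect_equal(g[which.max(v)], 180)
  # trapezoid quadrature recovers the season total
  integral <- sum((v[-1L] + v[-length(v)]) / 2) * 0.01
  expect_equal(integral, 500, tolerance = 1e-6)

  sn0 <- abundance_shape("skew_normal", 180, 10, shape = 0,
                         total_abundance = 500)
  expect_equal(evaluate_abundance(sn0, g), v, tolerance = 1e-12)

  expect_error(evaluate_abundance(shp, seq(160, 200, by = 0.01)),
               "truncates")
  expect_error(abundance_shape("gaussian", 180, 10, shape = 2), "shape")
  expect_error(abundance_shape("gaussian", 180, -1), "scale_days")
})

test_that("skew-normal moments and the matched gaussian are correct", {
  shp <- abundance_shape("skew_normal", 170, 12, shape = 5)
  m <- shape_moments(shp)
  g <- seq(170 - 6 * 12, 170 + 6 * 12, by = 0.01)
  v <- evaluate_abundance(shp, g)
  w <- v / sum(v)
  expect_equal(m[["mean"]], sum(g * w), tolerance = 1e-4)
  expect_equal(m[["sd"]], sqrt(sum((g - sum(g * w))^2 * w)), tolerance = 1e-4)
  mg <- matched_gaussian(shp)
  expect_equal(unname(shape_moments(mg)), unname(m))
})

test_that("a flat weight line leaves the 50% date unchanged, a rising one
           delays biomass", {
  g <- seq(100, 260, by = 0.01)
  shp <- abundance_shape("gaussian", 180, 10)
  a <- evaluate_abundance(shp, g)

  flat <- weight_line(2.5, 0, 120)
  b <- biomass_from_abundance(a, flat, g)
  expect_equal(b, 2.5 * a)
  expect_lt(abs(median_date(g, b) - median_date(g, a)), 1e-9)

  rising <- weight_line(1, 0.03, 120)
  b2 <- biomass_from_abundance(a, rising, g)
  expect_gt(median_date(g, b2), median_date(g, a))

  steep <- weight_line(0.5, 0.03, 170)  # negative below DOY ~153
  expect_error(biomass_from_abundance(a, steep, g), "nonpositive")
  expect_error(weight_line(0, 0.1), "intercept")
})

test_that("right skew enlarges the currency gap relative to the matched
           symmetric case", {
  skw <- abundance_shape("skew_normal", 150, 26, shape = 8)
  sym <- matched_gaussian(skw)
  g <- seq(20, 280, by = 0.01)  # covers +-5 scale units of both shapes
  wl <- weight_line(1, 0.03, 20)
  gap <- function(s) {
    a <- evaluate_abundance(s, g)
    b <- biomass_from_abundance(a, wl, g)
    median_date(g, b) - median_date(g, a)
  }
  expect_gt(gap(skw), gap(sym))
})

test_that("scenario specs enforce their slope regimes", {
  expect_error(scenario_spec("I", weight_slopes = c(1, 2, 3, 4, 5) / 100),
               "equal slopes")
  expect_error(scenario_spec("II", weight_slopes = rep(0.02, 5L)),
               "strictly increasing")
  expect_error(scenario_spec("III", weight_slopes = rep(0.02, 5L)),
               "strictly decreasing")
  expect_error(scenario_spec("custom"), "explicit weight_slopes")
  expect_error(scenario_spec("II", weight_slopes = c(-0.01, 0.01, 0.02,
                                                     0.03, 0.04)),
               "nonnegative")
})

test_that("the three canonical regimes order the currency rates as expected", {
  res <- lapply(c("I", "II", "III"),
                function(l) run_scenario(scenario_spec(l)))
  names(res) <- c("I", "II", "III")
  # I: constant mass-date slope, rates agree
  expect_lt(abs(res$I$rate_difference), 0.05)
  expect_equal(compare_rates(res$I)$classification, "equal within tol")
  # II: steepening slope, biomass peak advances more slowly
  expect_gt(res$II$rate_difference, 0.2)
  expect_equal(compare_rates(res$II)$classification, "biomass slower")
  # III: flattening slope, biomass peak advances faster
  expect_lt(res$III$rate_difference, -0.2)
  expect_equal(compare_rates(res$III)$classification, "biomass faster")
  # abundance rate equals the imposed advance in every scenario
  for (r in res) expect_equal(r$rate_abundance, -2, tolerance = 1e-3)
})

test_that("the regime ordering is robust across advances and slope ranges", {
  for (adv in c(0.5, 1.5, 3)) {
    for (mult in c(1, 1.5)) {
      # steepest slope kept positive over the widest (advance = 3) grid
      up <- scenario_spec("II", advance_days_per_year = adv,
                          weight_slopes = 0.003 * mult * 2^(0:4))
      dn <- scenario_spec("III", advance_days_per_year = adv,
                          weight_slopes = rev(0.003 * mult * 2^(0:4)))
      eq <- scenario_spec("I", advance_days_per_year = adv)
      expect_gt(run_scenario(up)$rate_difference, 0.05)
      expect_lt(run_scenario(dn)$rate_difference, -0.05)
      expect_lt(abs(run_scenario(eq)$rate_difference), 0.05)
    }
  }
})

test_that("mirroring the slope schedule in time flips the sign of the rate
           difference", {
  slopes <- c(0.006, 0.012, 0.024, 0.048, 0.07)
  fwd <- run_scenario(scenario_spec("custom", weight_slopes = slopes))
  rev_ <- run_scenario(scenario_spec("custom", weight_slopes = rev(slopes)))
  expect_gt(fwd$rate_difference, 0)
  expect_lt(rev_$rate_difference, 0)
})

test_that("positive weight slopes delay biomass for randomized unimodal
           shapes", {
  set.seed(14)
  for (i in 1:25) {
    loc <- runif(1, 170, 195)
    sc <- runif(1, 5, 14)
    al <- sample(c(0, 2, 5), 1L)
    shp <- abundance_shape(if (al == 0) "gaussian" else "skew_normal",
                           loc, sc, shape = al)
    g <- seq(loc - 6 * sc, loc + 6 * sc, by = 0.01)
    wl <- weight_line(1, runif(1, 0.002, 0.05), min(g))
    a <- evaluate_abundance(shp, g)
    b <- biomass_from_abundance(a, wl, g)
    expect_gte(median_date(g, b), median_date(g, a))
  }
})

test_that("halving the grid step moves the dates by less than 0.01 day", {
  sp <- scenario_spec("II")
  coarse <- run_scenario(sp, grid_step = 0.02)
  fine <- run_scenario(sp, grid_step = 0.01)
  expect_lt(max(abs(coarse$per_year$abundance_date -
                      fine$per_year$abundance_date)), 0.01)
  expect_lt(max(abs(coarse$per_year$biomass_date -
                      fine$per_year$biomass_date)), 0.01)
})
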