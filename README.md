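# phenocurrency

Tools for quantifying how the **currency** used to measure resource
phenology — specimen **abundance** versus community **biomass** — changes
inferences about consumer–resource synchrony, built around the arctic
shorebird / tundra-arthropod system but generic in its inputs.

When mean body mass per specimen rises through the season (light taxa
emerge early, heavy taxa late), the day on which 50% of the season's
cumulative resource has accrued falls *later* for biomass than for
abundance. A consumer hatching between the two dates is "late" in one
currency and "early" in the other, and year-varying mass–date relations
can even make the two currencies *advance at different rates*. The package
implements, with a tested synthetic-data generator providing analytic
ground truth:

* **Biomass reconstruction** from interval-based pitfall-trap counts:
  uniform spreading of interval catches over trap-days inside a fixed
  seasonal window (default DOY 157–238), per-specimen length assignment
  from auxiliary length tables, power-law allometry *W = a·L^b*, and
  averaging over active traps (`spread_interval_catches()`,
  `assign_lengths()`, `length_to_mass()`, `reconstruct_daily_series()`).
* **Cumulative-threshold phenology**: the real-valued day at which the
  linearly interpolated cumulative curve first reaches 50%
  (`median_date()`, `phenology_estimates()`), plus a penalized
  cubic-spline smooth of per-specimen mass against date
  (`seasonal_bodymass_smooth()`).
* **Chick aging**: a three-parameter logistic growth curve
  *m(t) = A / (1 + e^(−K(t−I)))* fitted by nonlinear least squares and
  inverted exactly to estimate family hatch dates from chick masses
  (`fit_logistic_growth()`, `age_from_mass()`, `family_hatch_date()`).
* **Synchrony trends**: mismatch = hatch median − resource median per year;
  OLS time trends with 95% percentile confidence intervals from a case
  bootstrap that resamples whole years (exact enumeration when the
  resample space is small, seeded Monte-Carlo otherwise;
  `mismatch_series()`, `ols_trend()`, `case_bootstrap()`,
  `trend_with_ci()`).
* **A conceptual simulator**: Gaussian or skew-normal abundance
  phenologies multiplied by linear mass–date "weight lines"; Scenarios
  I/II/III (constant / steepening / flattening slopes) generate equal,
  slower, or faster biomass rates of phenological change
  (`abundance_shape()`, `weight_line()`, `run_scenario()`,
  `compare_rates()`).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data. `analysis/01_generate_data.R` builds a 20-year, 6-plot × 4-trap
weekly pitfall design over a four-taxon community calibrated to a true
biomass−abundance lag of ~7 d, then:

```sh
Rscript analysis/01_generate_data.R
Rscript analysis/02_reconstruct_biomass.R
Rscript analysis/03_phenology_metrics.R
Rscript analysis/04_hatch_dates.R
Rscript analysis/05_synchrony_trends.R
Rscript analysis/06_currency_scenarios.R
```

Script 03 prints the per-year 50% dates for both currencies and the
recovery of the generator's analytic truth:

```
mean estimated lag: 6.9 d
mean true lag:      6.86 d
mean abs recovery error: 0.13 d
body-mass smooth: 0.42 mg at DOY 160 rising to 1.77 mg at DOY 236
```

Script 05 fits the mismatch trends. On the default synthetic study the two
currencies reverse the sign of the mean mismatch (hatching after the
abundance median but before the biomass median) while agreeing on its
trend, and the difference of the mean mismatches recovers the currency
lag:

```
Mismatch trend (abundance), n = 20 years
  slope:          0.532 d/yr  [0.460, 0.609]
  intercept:     -0.453 d     [-1.111, 1.529]
  mean mismatch:  4.599 d     [3.137, 5.966]
Mismatch trend (biomass), n = 20 years
  slope:          0.581 d/yr  [0.507, 0.659]
  intercept:     -7.827 d     [-8.556, -5.713]
  mean mismatch: -2.306 d     [-3.889, -0.809]
mean currency gap implied by the mismatches: 6.90 d
```

Script 06 runs the conceptual scenarios:

```
Currency scenario II (5 years)
 year weight_slope abundance_date biomass_date gap_days
    1        0.005        179.995      180.379 0.383762
    2        0.010        177.995      178.627 0.631945
    3        0.020        175.995      176.936 0.940617
    4        0.040        173.995      175.260 1.264838
    5        0.080        171.995      173.533 1.538198
rate of change: abundance -2.0000, biomass -1.7065 d/yr (difference +0.2935)
  -> biomass slower
```

i.e. with a steepening mass–date slope the biomass peak advances ~0.3 d/yr
more slowly than the abundance peak; Scenario I gives equal rates
(difference +0.018 d/yr) and Scenario III the reverse (−0.250 d/yr).

Everything is also available as a single call:

```r
library(phenocurrency)
res <- run_pipeline(list(seed = 42L), outdir = "results/run")
res$trends$biomass
```

## Data formats

Plain CSV with header rows, UTF-8, dates as day-of-year only:
`catches.csv` (year, doy_start, doy_end, plot, trap, taxon, life_stage,
count), `lengths.csv` (taxon, life_stage, length_mm), `allometry.csv`
(taxon, coeff_a, exponent_b), `nests.csv` (year, hatch_doy), `chicks.csv`
(chick_id, age_days, mass_g). `validate_tables()` checks schemas, ranges
and referential integrity before any computation; `run_pipeline()` writes
a manifest (config hash, per-stage seeds, record counts) alongside every
run. See the vignette (`vignettes/currency-dependent-phenology.Rmd`) for
the full model description and design rationale.
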