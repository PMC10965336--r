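#!/usr/bin/env Rscript
# Reconstruct daily abundance (specimens per trap-day) and biomass (mg per
# trap-day) series from the interval catch records: spread each interval
# catch uniformly over its in-window trap-days, weight specimen-equivalents
# by the expected mass from the taxon's length table and allometry, and
# average across active traps. Writes results/daily_series.csv.

library(phenocurrency)

catches <- read_table_csv("results/data/catches.csv", "catches")
lengths <- read_table_csv("results/data/lengths.csv", "lengths")
allometry <- read_table_csv("results/data/allometry.csv", "allometry")
validate_tables(catches, lengths, allometry)

daily <- reconstruct_daily_series(catches, lengths, allometry,
                                  mode = "expected")
write_table_csv(daily, "results/daily_series.csv", "daily_series")

em <- expected_specimen_mass(lengths, allometry)
cat("expected specimen mass by taxon (mg):\n")
print(em, row.names = FALSE, digits = 3)
for (cur in c("abundance", "biomass")) {
  s <- daily[daily$currency == cur, ]
  cat(sprintf("%-9s: mean daily value %.3f, season total per year %.1f\n",
              cur, mean(s$value, na.rm = TRUE),
              sum(s$value, na.rm = TRUE) / length(unique(s$year))))
}
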