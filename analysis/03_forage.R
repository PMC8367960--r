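#!/usr/bin/env Rscript
# Grazing assessment: per-species forage yields over the 4.235 km2 grazing
# area, standard dry forage at 50% utilization, carrying capacity over the
# 153-day season, the cow units actually grazing, the surplus to control,
# and the multi-year cow-unit trend.
library(bugyal)

species <- forage_species_table()
census2019 <- livestock_census_2019()
ga <- grazing_assessment(species, census2019)

cat(sprintf("total forage yield:  %.2f quintal/yr\n", ga$total_yield))
cat(sprintf("standard dry forage: %d quintal/yr\n", as.integer(ga$standard_forage)))
cat(sprintf("grazing capacity:    %d cow units/yr\n", ga$capacity))
cat(sprintf("2019 census:         %d cow units (raw %.1f)\n",
            ga$total_cu, to_cow_units(census2019)$raw_total))
cat(sprintf("surplus to control:  %d cow units\n", ga$deficit))

# trend over the simulated census (declining migratory pressure)
liv <- read.csv("results/sim/livestock.csv", stringsAsFactors = FALSE)
years <- sort(unique(liv$year))
totals <- vapply(years, function(y) to_cow_units(liv[liv$year == y, ])$total,
                 numeric(1))
tr <- cu_trend(years, totals)
cat(sprintf("cow-unit trend:      %+.1f CU/yr over %d-%d\n",
            tr$slope, min(years), max(years)))

write.csv(
  data.frame(
    quantity = c("total_yield_quintal", "standard_forage_quintal",
                 "capacity_cu", "census_cu", "surplus_cu", "trend_cu_per_yr"),
    value = c(ga$total_yield, ga$standard_forage, ga$capacity, ga$total_cu,
              ga$deficit, tr$slope)
  ),
  "results/forage.csv", row.names = FALSE
)
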