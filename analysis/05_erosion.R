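#!/usr/bin/env Rscript
# Check-dam sediment accounting: debris mass per dam from stored volume and
# triplicate core bulk densities, totalled and normalised over the 338 ha
# meadow to a t/ha/yr erosion-control rate.
library(bugyal)

dams <- read.csv("results/sim/checkdams.csv", stringsAsFactors = FALSE)
s <- erosion_summary(dams, area_ha = default_config()$erosion$area_ha)

cat(sprintf("%d check dams across %d gullies\n",
            s$n_dams, length(unique(dams$gully))))
cat(sprintf("total retained debris: %.2f t/yr\n", s$total_mass_t))
cat(sprintf("erosion-control rate:  %.1f t/ha/yr over %.0f ha\n",
            s$rate_t_ha_yr, s$area_ha))

write.csv(s$per_dam, "results/erosion_per_dam.csv", row.names = FALSE)
write.csv(data.frame(n_dams = s$n_dams, total_mass_t = s$total_mass_t,
                     area_ha = s$area_ha, rate_t_ha_yr = s$rate_t_ha_yr),
          "results/erosion.csv", row.names = FALSE)
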