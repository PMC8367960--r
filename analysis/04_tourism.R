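#!/usr/bin/env Rscript
# Tourist carrying capacity: correction factors from the simulated daily
# weather and from the published day counts, PCC/RCC for the 12% and 15%
# area scenarios, compliance with the 200/day cap, and the visitor-trend
# projection to 2025.
library(bugyal)

cfg <- default_config()$tourism

# factors from the published 2017-2019 window counts (used for capacity)
wc <- weather_window_counts()
cfs <- lapply(seq_len(nrow(wc)), function(i) {
  correction_factor(wc$variable[i], wc$limiting_days[i], wc$total_days[i])
})
cat(sprintf("correction factors: rain %.2f, snow %.2f\n",
            cfs[[1]]$value, cfs[[2]]$value))

# cross-check against the simulated daily series
w <- read.csv("results/sim/weather.csv", stringsAsFactors = FALSE)
cat(sprintf("simulated-series factors: rain %.3f, snow %.3f (raw)\n",
            correction_factor_from_weather(w, "rain")$raw,
            correction_factor_from_weather(w, "snow")$raw))

rows <- lapply(cfg$tourism_fractions, function(fr) {
  r <- rcc(pcc(tourism_config(cfg$total_area_m2, cfg$fragile_area_m2, fr,
                              cfg$area_per_tourist_m2, cfg$open_hours,
                              cfg$visit_hours)), cfs, cfg$days_per_year)
  cat(sprintf("scenario %2.0f%%: PCC %s, RCC %s/yr, %d/day\n", 100 * fr,
              format(r$pcc, big.mark = ","),
              format(r$rcc_year, big.mark = ","), r$rcc_day))
  data.frame(fraction = fr, pcc = r$pcc, rcc_year = r$rcc_year,
             rcc_day = r$rcc_day)
})
scen <- do.call(rbind, rows)

cp <- compliance(max(scen$rcc_day), current_daily_visits = 54,
                 cap = cfg$regulatory_cap_per_day)
cat(sprintf("current load 54/day vs binding limit %d: %s (headroom %d)\n",
            cp$binding_limit, ifelse(cp$compliant, "compliant", "EXCEEDED"),
            cp$headroom))

vis <- read.csv("results/sim/visitors.csv", stringsAsFactors = FALSE)
pr <- project_visitors(vis$year, vis$count, 2025)
cat(sprintf("visitor trend: %+.0f/yr; projected %s by 2025\n",
            pr$slope, format(pr$projected, big.mark = ",")))

write.csv(scen, "results/tourism.csv", row.names = FALSE)
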