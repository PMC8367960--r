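#!/usr/bin/env Rscript
# Multi-criteria restoration scorecard: score the management variables from
# the computed stages, the environmental variables from the simulated soil
# chemistry, and the socio-economic variables from the simulated survey;
# combine into category indices, the restoration evaluation index, and
# per-zone ecosystem index scores.
library(bugyal)

cr <- default_criteria()
forage <- read.csv("results/forage.csv", stringsAsFactors = FALSE)
erosion <- read.csv("results/erosion.csv", stringsAsFactors = FALSE)
soil <- read.csv("results/sim/soil.csv", stringsAsFactors = FALSE)
survey <- read.csv("results/sim/survey.csv", stringsAsFactors = FALSE)

val <- function(q) forage$value[forage$quantity == q]

m_scores <- list(
  score_variable(val("census_cu"), "grazing_control", cr),
  score_variable(54, "tourist_control", cr),
  score_variable(erosion$rate_t_ha_yr, "erosion_control", cr)
)
M <- category_index(m_scores)

scoreable <- intersect(unique(soil$variable), unique(cr$variable))
gtz <- soil[soil$zone == "GTZ" & soil$variable %in% scoreable, ]
e_scores <- lapply(unique(gtz$variable), function(v) {
  score_variable(mean(gtz$value[gtz$variable == v]), v, cr)
})
E <- category_index(e_scores)

SE <- category_index(aggregate_survey(survey)$variable_scores$score)

ev <- evaluation_index(c(M$raw_sum, E$raw_sum, SE$raw_sum))
cat(sprintf("category indices: M %.2f, E %.2f, SE %.2f\n",
            M$index, E$index, SE$index))
cat(sprintf("raw category sums: M %.1f + E %.1f + SE %.1f = %.1f\n",
            M$raw_sum, E$raw_sum, SE$raw_sum,
            M$raw_sum + E$raw_sum + SE$raw_sum))
cat(sprintf("restoration evaluation index: %.2f", ev))
if (ev == 100) cat("  (raw sum exceeds the 16-point maximum; clamped)")
cat("\n")

zones <- lapply(c("R", "GTZ", "UTZ"), function(z) {
  zv <- soil[soil$zone == z & soil$variable %in% scoreable,
             c("replicate", "variable", "value")]
  ecosystem_index(zv, zone = z, criteria = cr)
})
rk <- rank_zones(zones)
cat("ecosystem index by zone (mean % +/- SE):\n")
print(rk)

out <- list(M = M, E = E, SE = SE, evaluation_index = ev, zone_scores = rk)
writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                            dataframe = "rows"),
           "results/scorecard.json")
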