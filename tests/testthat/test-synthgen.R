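test_that("exact-mode quadrats reproduce target density and frequency", {
  vs <- vegetation_stats_table()
  for (z in c("R", "GTZ", "UTZ")) {
    t <- vs[vs$zone == z, c("species", "density", "frequency_pct")]
    obs <- gen_quadrats(t, n_quadrats = 30, seed = 21, exact = TRUE, zone = z)
    st <- compute_species_stats(obs, survey_design(30))
    m <- merge(t, st, by = "species")
    expect_equal(nrow(m), nrow(t))
    # printed targets are themselves 2-decimal roundings of k/30 values, so
    # recovery is exact at the table's printed precision
    expect_equal(round_half_up(m$density.y, 2), m$density.x)
    expect_equal(round_half_up(m$frequency_pct.y, 2),
                 round_half_up(m$frequency_pct.x, 2))
  }
  # absent species generate nothing
  none <- gen_quadrats(data.frame(species = "x", density = 0,
                                  frequency_pct = 0), seed = 1)
  expect_equal(nrow(none), 0)
  expect_error(gen_quadrats(data.frame(species = "x", density = 1,
                                       frequency_pct = 120)), "frequency")
})

test_that("stochastic quadrat counts recover the target density on average", {
  target <- data.frame(species = "a", density = 1.40, frequency_pct = 73.33)
  dens <- vapply(1:200, function(i) {
    obs <- gen_quadrats(target, seed = 3000 + i, exact = FALSE)
    compute_species_stats(obs, survey_design(30))$density
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 1.40), 3 * se + 1 / 60)  # + integer-target quantisation
})

test_that("generated weather matches the heavy-day probabilities", {
  w0 <- gen_weather("2018-01-01", "2018-12-31", p_rain = 0, p_snow = 0, seed = 2)
  expect_equal(correction_factor_from_weather(w0, "rain")$value, 1)
  expect_equal(correction_factor_from_weather(w0, "snow")$value, 1)
  w1 <- gen_weather("2018-01-01", "2018-12-31", p_rain = 1, p_snow = 1, seed = 2)
  expect_equal(correction_factor_from_weather(w1, "rain")$value, 0)
  expect_equal(correction_factor_from_weather(w1, "snow")$value, 0)
  w <- gen_weather("2017-01-01", "2019-12-31", p_rain = 369 / 909,
                   p_snow = 51 / 186, seed = 17)
  expect_lt(abs(correction_factor_from_weather(w, "rain")$raw - 0.594), 0.04)
  expect_true(all(w$rain_mm >= 0 & w$snow_cm >= 0))
  # snowfall only in the winter window
  m <- as.integer(format(as.Date(w$date), "%m"))
  expect_true(all(w$snow_cm[!(m %in% c(12, 1, 2))] == 0))
})

test_that("livestock generator hits cow-unit targets through the census stage", {
  # noiseless slope recovered exactly
  cen <- gen_livestock(2015:2019, intercept = 180, slope = -20, sigma = 0,
                       seed = 5)
  yrs <- sort(unique(cen$year))
  totals <- vapply(yrs, function(y) {
    to_cow_units(cen[cen$year == y, ])$total
  }, numeric(1))
  expect_equal(cu_trend(yrs, totals)$slope, -20)
  # calibration: the 2019 total of the default trend is exactly 881 CU
  cal <- gen_livestock(2010:2019, intercept = 1061, slope = -20, sigma = 0,
                       seed = 5)
  expect_equal(to_cow_units(cal[cal$year == 2019, ])$total, 881)
  # noisy recovery at documented scale: slope 33, sigma 10, n 10
  noisy <- gen_livestock(2010:2019, intercept = 300, slope = 33, sigma = 10,
                         seed = 12)
  tot <- vapply(2010:2019, function(y) {
    to_cow_units(noisy[noisy$year == y, ])$total
  }, numeric(1))
  expect_lt(abs(cu_trend(2010:2019, tot)$slope - 33), 10)
})

test_that("check-dam generator calibrates the total retained mass exactly", {
  d <- gen_checkdams(n = 38, target_total_t = 169.64, seed = 1)
  expect_equal(erosion_summary(d, 338)$total_mass_t, 169.64)
  expect_equal(length(unique(d$gully)), 3)
  one <- gen_checkdams(n = 1, target_total_t = 5, seed = 1)
  expect_equal(erosion_summary(one, 1)$total_mass_t, 5)
  zero <- gen_checkdams(n = 4, target_total_t = 0, seed = 1)
  expect_equal(erosion_summary(zero, 1)$total_mass_t, 0)
  expect_error(gen_checkdams(target_total_t = -1), "target total")
})

test_that("soil generator respects means, dispersions and physical ranges", {
  zt <- soil_zone_table()
  exact <- gen_soil(transform(zt, se = 0), n_replicates = 2, seed = 3)
  m <- merge(exact, zt, by = c("zone", "variable"))
  expect_equal(m$value, m$mean)
  # CLT bound at n = 200: |mean - mu| < 3 * 0.28 / sqrt(200) ~ 0.06
  gtz_ph <- zt[zt$zone == "GTZ" & zt$variable == "pH", ]
  big <- gen_soil(gtz_ph, n_replicates = 200, seed = 8)
  expect_lt(abs(mean(big$value) - 4.96), 0.06)
  # truncation keeps impossible values out
  odd <- data.frame(zone = "Z", variable = "WHC", mean = 1, se = 5)
  x <- gen_soil(odd, n_replicates = 100, seed = 2)
  expect_true(all(x$value >= 0))
})

test_that("survey generator draws valid multinomial ratings", {
  all_h <- gen_survey(c(L = 0, M = 0, H = 1), n_respondents = 5, seed = 1)
  expect_true(all(all_h$rating == "H"))
  expect_equal(aggregate_survey(all_h)$variable_scores$score, rep(3, 11))
  all_l <- gen_survey(c(L = 1, M = 0, H = 0), n_respondents = 5, seed = 1)
  expect_equal(aggregate_survey(all_l)$variable_scores$score, rep(0, 11))
  expect_error(gen_survey(c(L = 0.5, M = 0.2, H = 0.2)), "sum to 1")
  # mean score oracle: 0.2*0 + 0.5*1.5 + 0.3*3 = 1.65 over 120 respondents
  sv <- gen_survey(c(L = 0.2, M = 0.5, H = 0.3), n_respondents = 60, seed = 6)
  agg <- aggregate_survey(sv)
  expect_lt(abs(mean(agg$variable_scores$score) - 1.65), 0.3)
})

test_that("identical seeds give identical datasets and distinct substreams", {
  d1 <- generate_dataset(seed = 42)
  d2 <- generate_dataset(seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_dataset(seed = 43)
  expect_false(identical(d1$weather, d3$weather))
  # substream isolation: the weather draw does not depend on other generators
  w_alone <- gen_weather("2017-01-01", "2019-12-31", p_rain = 369 / 909,
                         p_snow = 51 / 186, seed = 42)
  expect_identical(d1$weather, w_alone)
})

test_that("generated datasets round-trip through CSV byte-identically", {
  dir1 <- file.path(tempdir(), "synth1")
  dir2 <- file.path(tempdir(), "synth2")
  unlink(c(dir1, dir2), recursive = TRUE)
  generate_dataset(seed = 7, out_dir = dir1)
  generate_dataset(seed = 7, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  # CSV write-then-read is lossless for the integer-valued schemas
  liv <- utils::read.csv(file.path(dir1, "livestock.csv"),
                         stringsAsFactors = FALSE)
  d <- generate_dataset(seed = 7)
  expect_equal(liv, d$livestock)
})
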