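#' Synthetic quadrat observations with target density and frequency
#'
#' Emulates a 30-quadrat vegetation survey. Each species occupies exactly
#' `round(frequency/100 * n)` quadrats, chosen uniformly at random. In exact
#' mode (the default, used for fixtures) the integer total
#' `round(density * n)` is spread as evenly as possible over the occupied
#' quadrats, so [compute_species_stats()] recovers the targets exactly. In
#' stochastic mode per-quadrat counts are drawn from a zero-truncated Poisson
#' whose mean equals the target individuals per occupied quadrat, so the
#' expected total matches the target density.
#'
#' @param targets data.frame with columns `species`, `density`,
#'   `frequency_pct` (per m2 / percent targets).
#' @param n_quadrats quadrats in the survey (default 30).
#' @param seed integer seed.
#' @param exact deterministic totals (default TRUE).
#' @param zone zone label stamped on the observations.
#' @return data.frame of observations: `zone`, `plot`, `quadrat`, `species`,
#'   `count`.
#' @export
gen_quadrats <- function(targets, n_quadrats = 30, seed = 1, exact = TRUE,
                         zone = "Z1") {
  validate_all(list(
    "density targets must be >= 0" = all(targets$density >= 0),
    "frequency targets must be in [0, 100]" =
      all(targets$frequency_pct >= 0 & targets$frequency_pct <= 100)
  ))
  set.seed(substream_seed(seed, "quadrats"))
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    occ <- as.integer(round_half_up(targets$frequency_pct[i] / 100 * n_quadrats))
    total <- as.integer(round_half_up(targets$density[i] * n_quadrats))
    if (occ == 0 || total == 0) next   # species absent
    if (total < occ) total <- occ      # every occupied quadrat holds >= 1
    quadrats <- sample.int(n_quadrats, occ)
    counts <- if (exact) {
      base <- rep(total %/% occ, occ)
      extra <- total %% occ
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
      base
    } else {
      rztpois(occ, mean_target = total / occ)
    }
    rows[[length(rows) + 1]] <- data.frame(
      zone = zone, plot = "P1", quadrat = paste0("Q", quadrats),
      species = targets$species[i], count = counts,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(zone = character(), plot = character(),
                      quadrat = character(), species = character(),
                      count = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# zero-truncated Poisson draws with a given (truncated) mean.
# The mean of a Poisson(lambda) conditioned on > 0 is lambda / (1 - exp(-lambda));
# lambda is solved by uniroot, and sampling rejects zeros.
rztpois <- function(n, mean_target) {
  stopifnot(mean_target >= 1)
  if (mean_target <= 1 + 1e-9) return(rep(1L, n))
  lambda <- stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean_target,
    interval = c(1e-8, mean_target * 2 + 10)
  )$root
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rpois(1, lambda)
      if (x > 0) break
    }
    out[i] <- x
  }
  out
}

#' Synthetic daily weather series
#'
#' Daily rainfall and snowfall with heavy-weather days placed as Bernoulli
#' events inside the relevant windows: heavy rain (> `rain_threshold` mm)
#' with probability `p_rain` on March-November days, heavy snow
#' (> `snow_threshold` cm) with probability `p_snow` on December-February
#' days. Heavy amounts sit above the threshold (threshold plus an exponential
#' excess); ordinary days sit strictly below it.
#'
#' @param start,end first and last date (Date or ISO string).
#' @param p_rain,p_snow daily heavy-rain / heavy-snow probabilities.
#' @param seed integer seed.
#' @param rain_threshold heavy-rain threshold, mm/day (default 250).
#' @param snow_threshold heavy-snow threshold, cm/day (default 8).
#' @return data.frame `date`, `rain_mm`, `snow_cm`.
#' @export
gen_weather <- function(start, end, p_rain, p_snow, seed = 1,
                        rain_threshold = 250, snow_threshold = 8) {
  validate_all(list(
    "probabilities must be in [0,1]" =
      p_rain >= 0 && p_rain <= 1 && p_snow >= 0 && p_snow <= 1,
    "start must not be after end" = as.Date(start) <= as.Date(end)
  ))
  set.seed(substream_seed(seed, "weather"))
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  m <- as.integer(format(dates, "%m"))
  n <- length(dates)
  rain <- numeric(n)
  snow <- numeric(n)
  in_rain <- m %in% 3:11
  in_snow <- m %in% c(12L, 1L, 2L)
  heavy_rain <- in_rain & stats::runif(n) < p_rain
  heavy_snow <- in_snow & stats::runif(n) < p_snow
  rain[in_rain] <- stats::runif(sum(in_rain), 0, rain_threshold * 0.99)
  rain[heavy_rain] <- rain_threshold +
    stats::rexp(sum(heavy_rain), rate = 1 / (rain_threshold * 0.1)) + 1e-6
  snow[in_snow] <- stats::runif(sum(in_snow), 0, snow_threshold * 0.99)
  snow[heavy_snow] <- snow_threshold +
    stats::rexp(sum(heavy_snow), rate = 1 / (snow_threshold * 0.25)) + 1e-6
  data.frame(date = dates, rain_mm = rain, snow_cm = snow)
}

# decompose an integer cow-unit target into head counts, using adult cows
# (AU = 1) as the filler so the rounded total reproduces the target exactly
decompose_cu <- function(target_cu, au_table) {
  au <- stats::setNames(au_table$animal_unit, au_table$animal)
  other <- setdiff(names(au), "cow")
  frac <- c(0.15, 0.08, 0.07)[seq_along(other)]
  counts <- stats::setNames(integer(length(au)), names(au))
  for (i in seq_along(other)) {
    counts[other[i]] <- max(0L, as.integer(round(frac[i] * target_cu / au[other[i]])))
  }
  cu_other <- sum(counts[other] * au[other])
  cows <- as.integer(round_half_up(target_cu - cu_other))
  if (cows < 0) {
    warning("cow-unit target ", target_cu,
            " infeasible for the drawn herd mix; clipping cows at 0")
    cows <- 0L
  }
  counts["cow"] <- cows
  counts
}

#' Synthetic livestock census with a linear cow-unit trend
#'
#' Draws annual cow-unit totals `intercept + slope * (year - min(year))`
#' plus Gaussian noise, splits each year's total between migratory and local
#' herds, and decomposes each origin's total into head counts consistent with
#' the animal-unit table (adult cows absorb the remainder, so
#' [to_cow_units()] on the census reproduces the yearly totals exactly).
#'
#' @param years integer vector of census years.
#' @param intercept cow units in the first year.
#' @param slope cow units per year.
#' @param sigma Gaussian noise standard deviation (0 = deterministic trend).
#' @param migratory_fraction fraction of each year's cow units carried by
#'   migratory herds (default 0.2).
#' @param au_table animal-unit table (default [animal_unit_table()]).
#' @param seed integer seed.
#' @return data.frame `year`, `animal`, `count`, `origin`.
#' @export
gen_livestock <- function(years, intercept, slope, sigma = 0,
                          migratory_fraction = 0.2,
                          au_table = animal_unit_table(), seed = 1) {
  stopifnot(length(years) >= 1, sigma >= 0,
            migratory_fraction >= 0, migratory_fraction <= 1)
  set.seed(substream_seed(seed, "livestock"))
  rows <- list()
  for (y in years) {
    target <- intercept + slope * (y - min(years)) + stats::rnorm(1, 0, sigma)
    target <- max(0, round_half_up(target))
    mig <- round_half_up(migratory_fraction * target)
    for (origin in c("migratory", "local")) {
      t_cu <- if (origin == "migratory") mig else target - mig
      counts <- decompose_cu(t_cu, au_table)
      rows[[length(rows) + 1]] <- data.frame(
        year = y, animal = names(counts), count = as.integer(counts),
        origin = origin, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic annual visitor counts with a linear trend
#'
#' @param years integer years.
#' @param intercept visitors in the first year.
#' @param slope visitors per year.
#' @param sigma Gaussian noise sd.
#' @param seed integer seed.
#' @return data.frame `year`, `count` (non-negative integers).
#' @export
gen_visitors <- function(years, intercept, slope, sigma = 0, seed = 1) {
  stopifnot(length(years) >= 1, sigma >= 0)
  set.seed(substream_seed(seed, "visitors"))
  counts <- intercept + slope * (years - min(years)) +
    stats::rnorm(length(years), 0, sigma)
  data.frame(year = years,
             count = pmax(0L, as.integer(round_half_up(counts))))
}

#' Synthetic check dams calibrated to a total retained mass
#'
#' Draws dam volumes and triplicate bulk densities uniformly within the given
#' ranges, assigns dams round-robin to gullies, then rescales all volumes so
#' the summed debris mass equals `target_total_t` exactly.
#'
#' @param n number of dams (default 38).
#' @param target_total_t total retained mass to calibrate to, tonnes.
#' @param volume_range volume range, m3 (default 0.5-8).
#' @param density_range bulk-density range, g/cm3 (default 1.2-1.7).
#' @param n_gullies gullies the dams are spread across (default 3).
#' @param seed integer seed.
#' @return data.frame `dam`, `gully`, `volume_m3`, `rho1`, `rho2`, `rho3`.
#' @export
gen_checkdams <- function(n = 38, target_total_t = 169.64,
                          volume_range = c(0.5, 8),
                          density_range = c(1.2, 1.7),
                          n_gullies = 3, seed = 1) {
  validate_all(list(
    "n must be >= 1" = n >= 1,
    "target total must be >= 0" = target_total_t >= 0
  ))
  set.seed(substream_seed(seed, "checkdams"))
  v <- stats::runif(n, volume_range[1], volume_range[2])
  rho <- matrix(stats::runif(3 * n, density_range[1], density_range[2]),
                ncol = 3)
  mass <- v * rowMeans(rho)
  scale <- if (sum(mass) > 0) target_total_t / sum(mass) else 0
  data.frame(
    dam = sprintf("D%02d", seq_len(n)),
    gully = paste0("G", (seq_len(n) - 1) %% n_gullies + 1),
    volume_m3 = v * scale,
    rho1 = rho[, 1], rho2 = rho[, 2], rho3 = rho[, 3],
    stringsAsFactors = FALSE
  )
}

#' Synthetic soil-chemistry replicates around zone means
#'
#' Gaussian draws per variable and zone, truncated to physical ranges (pH in
#' [0, 14]; percentage variables in [0, 100]; other variables non-negative)
#' by resampling, with clipping as a last resort. The supplied dispersion is
#' used as the replicate-level standard deviation.
#'
#' @param zone_table data.frame `zone`, `variable`, `mean`, `se`.
#' @param n_replicates replicates per zone and variable (default 3).
#' @param seed integer seed.
#' @return data.frame `zone`, `variable`, `replicate`, `value`.
#' @export
gen_soil <- function(zone_table, n_replicates = 3, seed = 1) {
  stopifnot(all(c("zone", "variable", "mean", "se") %in% names(zone_table)),
            all(zone_table$se >= 0), n_replicates >= 1)
  set.seed(substream_seed(seed, "soil"))
  pct_vars <- c("OC", "N", "P", "K", "WHC", "vegetation_cover")
  rows <- lapply(seq_len(nrow(zone_table)), function(i) {
    v <- zone_table$variable[i]
    lim <- if (v == "pH") c(0, 14) else if (v %in% pct_vars) c(0, 100) else c(0, Inf)
    x <- stats::rnorm(n_replicates, zone_table$mean[i], zone_table$se[i])
    for (attempt in 1:100) {
      bad <- x < lim[1] | x > lim[2]
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), zone_table$mean[i], zone_table$se[i])
    }
    x <- pmin(pmax(x, lim[1]), lim[2])
    data.frame(zone = zone_table$zone[i], variable = v,
               replicate = seq_len(n_replicates), value = x,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic socio-economic survey responses
#'
#' Respondents are assigned to villages and the three age classes, and each
#' rates every variable on the low/moderate/high scale by a multinomial draw.
#'
#' @param probs named numeric vector `c(L=, M=, H=)` summing to 1, or a
#'   data.frame `variable`, `L`, `M`, `H` for per-variable probabilities.
#' @param n_respondents respondents per village (default 60).
#' @param villages village labels (default Barsu and Raithal).
#' @param variables rated variables (default the 11 socio-economic
#'   feasibility variables, see [se_variables()]).
#' @param seed integer seed.
#' @return data.frame `respondent`, `village`, `age_group`, `variable`,
#'   `rating`.
#' @export
gen_survey <- function(probs = c(L = 0.1, M = 0.3, H = 0.6),
                       n_respondents = 60,
                       villages = c("Barsu", "Raithal"),
                       variables = se_variables(), seed = 1) {
  if (is.data.frame(probs)) {
    stopifnot(all(c("variable", "L", "M", "H") %in% names(probs)))
    psums <- rowSums(probs[, c("L", "M", "H")])
  } else {
    stopifnot(all(c("L", "M", "H") %in% names(probs)))
    psums <- sum(probs[c("L", "M", "H")])
  }
  if (any(abs(psums - 1) > 1e-8) || any(unlist(probs[setdiff(names(probs), "variable")]) < 0)) {
    stop("rating probabilities must be non-negative and sum to 1")
  }
  set.seed(substream_seed(seed, "survey"))
  age_groups <- c("20-40", "40-60", ">60")
  rows <- list()
  rid <- 0
  for (v in villages) {
    for (r in seq_len(n_respondents)) {
      rid <- rid + 1
      age <- sample(age_groups, 1)
      for (var in variables) {
        p <- if (is.data.frame(probs)) {
          as.numeric(probs[probs$variable == var, c("L", "M", "H")])
        } else probs[c("L", "M", "H")]
        rows[[length(rows) + 1]] <- data.frame(
          respondent = sprintf("R%03d", rid), village = v, age_group = age,
          variable = var,
          rating = sample(c("L", "M", "H"), 1, prob = p),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The eleven socio-economic feasibility variables
#' @return character vector of variable names.
#' @export
se_variables <- function() {
  c("cost_effectiveness", "economic_efficiency", "procedural_equity",
    "social_preference", "adoption_lag", "replicability",
    "technical_sophistication", "cultural_values", "social_norms",
    "policy_legislation", "governance_mechanism")
}

#' Generate a complete synthetic input dataset
#'
#' Runs every generator with substreams of one root seed and (optionally)
#' writes the tables plus a manifest recording the seed. Identical seeds
#' yield byte-identical outputs.
#'
#' @param seed root integer seed.
#' @param out_dir directory to write CSVs into (NULL = don't write).
#' @param config project configuration (default [default_config()]).
#' @return named list of data.frames: `quadrats` (one per zone), `weather`,
#'   `livestock`, `visitors`, `checkdams`, `soil`, `survey`.
#' @export
generate_dataset <- function(seed = 42, out_dir = NULL,
                             config = default_config()) {
  veg <- vegetation_stats_table()
  quadrats <- do.call(rbind, lapply(unique(veg$zone), function(z) {
    t <- veg[veg$zone == z, c("species", "density", "frequency_pct")]
    gen_quadrats(t, n_quadrats = 30,
                 seed = substream_seed(seed, paste0("zone-", z)),
                 exact = TRUE, zone = z)
  }))
  weather <- gen_weather("2017-01-01", "2019-12-31",
                         p_rain = 369 / 909, p_snow = 51 / 186, seed = seed)
  livestock <- gen_livestock(2010:2019, intercept = 1061, slope = -20,
                             sigma = 0, seed = seed)
  visitors <- gen_visitors(2015:2019, intercept = 7200, slope = 2850,
                           sigma = 300, seed = seed)
  checkdams <- gen_checkdams(seed = seed)
  soil <- gen_soil(soil_zone_table(), n_replicates = 3, seed = seed)
  survey <- gen_survey(seed = seed)
  out <- list(quadrats = quadrats, weather = weather, livestock = livestock,
              visitors = visitors, checkdams = checkdams, soil = soil,
              survey = survey)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    writeLines(
      jsonlite::toJSON(list(seed = seed, tables = names(out)),
                       auto_unbox = TRUE, pretty = TRUE),
      file.path(out_dir, "manifest.json")
    )
  }
  invisible(out)
}
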