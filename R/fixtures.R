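# Packaged field tables. All accessors read the plain-text fixtures shipped
# under extdata; the synthetic livestock census is a constructed stand-in for
# an unpublished herd composition, calibrated so the 2019 total is 881 CU.

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "bugyal")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("packaged fixture not found: ", file)
  path
}

#' Packaged forage-species table
#'
#' The 37 dominant palatable species with mean density, above-ground dry
#' biomass and the published per-species forage yield. Rows whose printed
#' yield is typographically inconsistent with the biomass column are flagged
#' `ambiguous`.
#'
#' @return data.frame `species`, `density`, `biomass_g_per_m2`,
#'   `yield_printed_quintal`, `palatable`, `ambiguous`.
#' @export
forage_species_table <- function() {
  utils::read.csv(extdata_path("forage_species.csv"), stringsAsFactors = FALSE)
}

#' Packaged per-zone vegetation statistics
#'
#' Density, frequency and abundance of the dominant herbs in the reference
#' (R), geo-coir treated (GTZ) and untreated degraded (UTZ) zones, at the
#' 2-decimal precision of the published table.
#'
#' @return data.frame `zone`, `species`, `density`, `frequency_pct`,
#'   `abundance`.
#' @export
vegetation_stats_table <- function() {
  utils::read.csv(extdata_path("vegetation_stats.csv"), stringsAsFactors = FALSE)
}

#' Packaged soil-chemistry zone means
#'
#' Mean and standard error per zone for total herb density, pH, organic
#' carbon, N, P, K and water holding capacity.
#'
#' @return data.frame `zone`, `variable`, `mean`, `se`.
#' @export
soil_zone_table <- function() {
  utils::read.csv(extdata_path("soil_zones.csv"), stringsAsFactors = FALSE)
}

#' Packaged animal-unit conversion table
#'
#' Body weight, daily dry-forage requirement (3 percent of body weight) and
#' cow-equivalent animal unit per livestock type.
#'
#' @return data.frame `animal`, `body_weight_kg`, `forage_req_kg_day`,
#'   `animal_unit`.
#' @export
animal_unit_table <- function() {
  utils::read.csv(extdata_path("animal_units.csv"), stringsAsFactors = FALSE)
}

#' Synthetic 2019 livestock census
#'
#' A constructed herd composition (the published census lives in unavailable
#' supplementary material) calibrated so that [to_cow_units()] with the
#' packaged animal-unit table returns exactly 881 cow units for 2019.
#'
#' @return data.frame `year`, `animal`, `count`, `origin`.
#' @export
livestock_census_2019 <- function() {
  utils::read.csv(extdata_path("synthetic_livestock_2019.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged heavy-weather day counts
#'
#' Limiting and total day counts for the 2017-2019 heavy-rain
#' (March-November) and heavy-snow (December-February) windows, as published;
#' used where raw daily series are unavailable.
#'
#' @return data.frame `variable`, `limiting_days`, `total_days`.
#' @export
weather_window_counts <- function() {
  utils::read.csv(extdata_path("weather_window_counts.csv"),
                  stringsAsFactors = FALSE)
}
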