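#' Default project configuration
#'
#' All named constants of the evaluation pipeline. Every stage reads its own
#' named area: the grazing area (4.235 km2, the value consistent with the
#' published per-species forage yields), the tourism areas (3.94 km2 total,
#' 12,000 m2 ecologically fragile), and the erosion-control extent (338 ha,
#' the 3.38 km2 meadow). A separately quoted grazing area of 3.235 km2 is
#' carried as `eq4_note_area_km2` for documentation; it is not used because it
#' cannot reproduce the published yields.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    vegdata = list(
      n_quadrats = 30L,
      quadrat_area_m2 = 1,
      dominant_k = 4L
    ),
    grazing = list(
      area_km2 = 4.235,
      eq4_note_area_km2 = 3.235,
      utilization_rate = 0.5,
      conversion_coefficient = 1,
      intake_kg_day = 7.5,
      grazing_days = 153L
    ),
    tourism = list(
      total_area_m2 = 3940000,
      fragile_area_m2 = 12000,
      tourism_fractions = c(0.12, 0.15),
      area_per_tourist_m2 = 5,
      open_hours = 6,
      visit_hours = 3,
      rain_threshold_mm = 250,
      snow_threshold_cm = 8,
      rain_months = 3:11,
      snow_months = c(12L, 1L, 2L),
      regulatory_cap_per_day = 200,
      days_per_year = 365
    ),
    erosion = list(
      area_ha = 338,
      core_radius_cm = 2.5,
      core_height_cm = 30
    ),
    scorecard = list(
      mid_score = 1.5,
      max_score = 16
    )
  )
}

#' Load a project configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration, overlays it on
#' [default_config()], rejects unknown keys (typo protection) and validates
#' all values at once, reporting every violation together.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(user)) {
    unknown_sections <- setdiff(names(user), names(cfg))
    if (length(unknown_sections)) {
      stop("unknown config sections: ", paste(unknown_sections, collapse = ", "))
    }
    for (section in names(user)) {
      unknown <- setdiff(names(user[[section]]), names(cfg[[section]]))
      if (length(unknown)) {
        stop("unknown keys in section '", section, "': ",
             paste(unknown, collapse = ", "))
      }
      cfg[[section]][names(user[[section]])] <- user[[section]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  validate_all(list(
    "vegdata$n_quadrats must be >= 1" = cfg$vegdata$n_quadrats >= 1,
    "vegdata$quadrat_area_m2 must be > 0" = cfg$vegdata$quadrat_area_m2 > 0,
    "grazing$area_km2 must be > 0" = cfg$grazing$area_km2 > 0,
    "grazing$utilization_rate must be in [0,1]" =
      cfg$grazing$utilization_rate >= 0 && cfg$grazing$utilization_rate <= 1,
    "grazing$intake_kg_day must be > 0" = cfg$grazing$intake_kg_day > 0,
    "grazing$grazing_days must be >= 1" = cfg$grazing$grazing_days >= 1,
    "tourism$total_area_m2 must be > 0" = cfg$tourism$total_area_m2 > 0,
    "tourism$fragile_area_m2 must be in [0, total]" =
      cfg$tourism$fragile_area_m2 >= 0 &&
        cfg$tourism$fragile_area_m2 <= cfg$tourism$total_area_m2,
    "tourism$tourism_fractions must be in (0,1]" =
      all(cfg$tourism$tourism_fractions > 0 & cfg$tourism$tourism_fractions <= 1),
    "tourism$area_per_tourist_m2 must be > 0" = cfg$tourism$area_per_tourist_m2 > 0,
    "tourism$regulatory_cap_per_day must be >= 0" =
      cfg$tourism$regulatory_cap_per_day >= 0,
    "erosion$area_ha must be > 0" = cfg$erosion$area_ha > 0,
    "scorecard$mid_score must be in [0,3]" =
      cfg$scorecard$mid_score >= 0 && cfg$scorecard$mid_score <= 3,
    "scorecard$max_score must be > 0" = cfg$scorecard$max_score > 0
  ))
  invisible(cfg)
}
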