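#' Tourism area configuration
#'
#' Carries the areas and timing that determine physical carrying capacity:
#' total geographical area, the ecologically fragile area excluded from use,
#' the fraction of the remaining available area opened to tourism, the area
#' required per tourist, and the rotation factor (daily open period over the
#' average visit length).
#'
#' @param total_area_m2 total geographical area, m2.
#' @param fragile_area_m2 ecologically fragile area excluded from tourism, m2.
#' @param tourism_fraction fraction of the available area open to tourism
#'   (the assessed scenarios use 0.12 and 0.15).
#' @param area_per_tourist_m2 m2 required per tourist (default 5, raised from
#'   the generic 3 m2 because the meadow is degradation-sensitive).
#' @param open_hours daily open period, hours (default 6).
#' @param visit_hours average visit length, hours (default 3).
#' @return an object of class `tourism_config`.
#' @export
tourism_config <- function(total_area_m2 = 3940000, fragile_area_m2 = 12000,
                           tourism_fraction = 0.15, area_per_tourist_m2 = 5,
                           open_hours = 6, visit_hours = 3) {
  validate_all(list(
    "fragile area cannot exceed total area" = fragile_area_m2 <= total_area_m2,
    "areas must be non-negative" = total_area_m2 >= 0 && fragile_area_m2 >= 0,
    "tourism_fraction must be in (0, 1]" =
      tourism_fraction > 0 && tourism_fraction <= 1,
    "area per tourist must be > 0" = area_per_tourist_m2 > 0,
    "hours must be > 0" = open_hours > 0 && visit_hours > 0
  ))
  structure(list(
    total_area_m2 = total_area_m2, fragile_area_m2 = fragile_area_m2,
    tourism_fraction = tourism_fraction,
    area_per_tourist_m2 = area_per_tourist_m2,
    open_hours = open_hours, visit_hours = visit_hours,
    rotation_factor = open_hours / visit_hours
  ), class = "tourism_config")
}

#' Physical carrying capacity (PCC)
#'
#' `PCC = A / Au * Rf`, where `A` is the tourism area (the configured
#' fraction of total minus fragile area), `Au` the area required per tourist
#' and `Rf` the rotation factor.
#'
#' @param config a [tourism_config()].
#' @return list with `available_area_m2`, `tourism_area_m2` (A), and `pcc`
#'   (visits/year).
#' @export
pcc <- function(config) {
  stopifnot(inherits(config, "tourism_config"))
  available <- config$total_area_m2 - config$fragile_area_m2
  a <- config$tourism_fraction * available
  list(available_area_m2 = available,
       tourism_area_m2 = a,
       pcc = a / config$area_per_tourist_m2 * config$rotation_factor)
}

#' Correction factor from limiting-day counts
#'
#' `Cfx = 1 - Lmx / Tmx`: the fraction of the season not lost to a limiting
#' condition. For capacity arithmetic the factor is truncated to two decimals
#' (rounding a capacity discount down is conservative; it also reproduces
#' conventional printed factors such as 1 - 51/186 -> 0.72). The raw value is
#' retained for diagnostics.
#'
#' @param name label of the limiting variable.
#' @param limiting_days days lost to the condition (Lmx).
#' @param total_days days in the window (Tmx).
#' @return list `name`, `limiting_days`, `total_days`, `raw`, `value`
#'   (2-decimal, used in the RCC product).
#' @export
correction_factor <- function(name, limiting_days, total_days) {
  validate_all(list(
    "total_days must be > 0" = total_days > 0,
    "limiting_days must be in [0, total_days]" =
      limiting_days >= 0 && limiting_days <= total_days
  ))
  raw <- 1 - limiting_days / total_days
  list(name = name, limiting_days = as.integer(limiting_days),
       total_days = as.integer(total_days),
       raw = raw, value = trunc_decimals(raw, 2))
}

#' Correction factor from a daily weather series
#'
#' Counts the days inside the relevant month window and those exceeding the
#' heavy-weather threshold, then applies [correction_factor()]. Defaults
#' follow the assessed windows: heavy rain > 250 mm/day over March-November,
#' heavy snow > 8 cm/day over December-February.
#'
#' @param records data.frame with columns `date` (Date or ISO string),
#'   `rain_mm`, `snow_cm`.
#' @param variable `"rain"` or `"snow"`.
#' @param threshold heavy-day threshold (mm for rain, cm for snow); defaults
#'   250 and 8.
#' @param months integer months of the window; defaults March-November for
#'   rain, December-February for snow.
#' @return a correction factor list as from [correction_factor()].
#' @export
correction_factor_from_weather <- function(records,
                                           variable = c("rain", "snow"),
                                           threshold = NULL, months = NULL) {
  variable <- match.arg(variable)
  stopifnot(all(c("date", "rain_mm", "snow_cm") %in% names(records)))
  threshold <- threshold %||% if (variable == "rain") 250 else 8
  months <- months %||% if (variable == "rain") 3:11 else c(12L, 1L, 2L)
  d <- as.Date(records$date)
  in_window <- as.integer(format(d, "%m")) %in% months
  if (!any(in_window)) {
    stop("no days fall inside the ", variable, " analysis window")
  }
  amount <- if (variable == "rain") records$rain_mm else records$snow_cm
  correction_factor(
    name = if (variable == "rain") "heavy_rain" else "heavy_snow",
    limiting_days = sum(in_window & amount > threshold),
    total_days = sum(in_window)
  )
}

#' Real carrying capacity (RCC)
#'
#' `RCC = PCC * (Cf1 * Cf2 * ... * Cfn)`, using the 2-decimal correction
#' factors, rounded half-up to whole visits per year; the daily capacity is
#' `floor(RCC_year / 365)`.
#'
#' @param pcc_result the list returned by [pcc()] (or a bare PCC number).
#' @param correction_factors list of factors from [correction_factor()]
#'   (may be empty: the empty product is 1 and RCC = PCC).
#' @param days_per_year divisor for the daily figure (default 365).
#' @return list `pcc`, `cf_product`, `rcc_year`, `rcc_day`,
#'   `correction_factors`.
#' @export
rcc <- function(pcc_result, correction_factors = list(), days_per_year = 365) {
  p <- if (is.list(pcc_result) && !is.null(pcc_result$pcc)) pcc_result$pcc else pcc_result
  vals <- vapply(correction_factors, function(cf) cf$value, numeric(1))
  if (length(vals) && any(vals < 0 | vals > 1)) {
    stop("correction factors must lie in [0, 1]")
  }
  prod_cf <- prod(vals)
  rcc_year <- round_half_up(p * prod_cf)
  list(pcc = p, cf_product = prod_cf,
       rcc_year = rcc_year,
       rcc_day = floor(rcc_year / days_per_year),
       correction_factors = correction_factors)
}

#' Regulatory compliance of current visitation
#'
#' Compares the current daily visitor load against the binding limit: the
#' smaller of the regulatory cap and the computed daily real carrying
#' capacity.
#'
#' @param rcc_day computed daily real carrying capacity.
#' @param current_daily_visits observed daily visitors.
#' @param cap regulatory cap, visits/day (default 200).
#' @return list `compliant`, `binding_limit`, `headroom`
#'   (binding limit minus current load; negative when exceeded).
#' @export
compliance <- function(rcc_day, current_daily_visits, cap = 200) {
  stopifnot(rcc_day >= 0, current_daily_visits >= 0, cap >= 0)
  limit <- min(cap, rcc_day)
  list(compliant = current_daily_visits <= limit,
       binding_limit = limit,
       headroom = limit - current_daily_visits)
}

#' Linear projection of annual visitor numbers
#'
#' Ordinary least-squares regression of annual visitor counts on calendar
#' year, evaluated at a target year.
#'
#' @param years calendar years (>= 2 distinct).
#' @param counts annual visitor counts.
#' @param target_year year at which to evaluate the projection.
#' @return list `projected` (integer count at the target year), `slope`
#'   (visitors per year), `intercept`, `fit`.
#' @export
project_visitors <- function(years, counts, target_year) {
  if (length(years) < 2 || length(unique(years)) < 2) {
    stop("at least two distinct years are needed to project visitors")
  }
  stopifnot(length(years) == length(counts), all(counts >= 0))
  fit <- stats::lm(counts ~ years)
  pred <- unname(stats::predict(fit, data.frame(years = target_year)))
  list(projected = as.integer(round_half_up(pred)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}
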