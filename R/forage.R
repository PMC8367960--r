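#' Forage yield of a species over the grazing area
#'
#' Converts a measured above-ground dry biomass (g per m2) to the annual
#' forage yield over the grazing area, in quintal (1 quintal = 100 kg):
#' `Y = Yp * A`, with the unit chain g/m2 x 1e6 m2/km2 / 1e5 g/quintal,
#' i.e. `Yp * A * 10`.
#'
#' @param biomass_g_m2 dry biomass in g/m2 (may be a vector, one per species).
#' @param area_km2 grazing area in km2.
#' @return forage yield in quintal per year.
#' @export
forage_yield <- function(biomass_g_m2, area_km2) {
  validate_all(list(
    "biomass must be >= 0" = all(biomass_g_m2 >= 0),
    "area must be >= 0"    = length(area_km2) == 1 && area_km2 >= 0
  ))
  biomass_g_m2 * area_km2 * 10
}

#' Standard dry forage from total yield
#'
#' `F = total_yield * Ui * Ci` where `Ui` is the utilization rate and `Ci`
#' the meadow conversion coefficient. The result is truncated toward zero for
#' whole-quintal reporting (10,003 x 0.5 = 5001.5 -> 5001), matching the
#' convention of rangeland capacity tables; the untruncated value is
#' available via `raw = TRUE`.
#'
#' @param total_yield total forage yield, quintal/year.
#' @param utilization_rate fraction of the yield actually usable (default 0.5).
#' @param conversion_coefficient meadow conversion coefficient (default 1).
#' @param raw return the untruncated product.
#' @return standard dry forage in quintal/year.
#' @export
standard_forage <- function(total_yield, utilization_rate = 0.5,
                            conversion_coefficient = 1, raw = FALSE) {
  validate_all(list(
    "total_yield must be >= 0" = all(total_yield >= 0),
    "utilization_rate must be in [0,1]" =
      utilization_rate >= 0 && utilization_rate <= 1,
    "conversion_coefficient must be >= 0" = conversion_coefficient >= 0
  ))
  f <- total_yield * utilization_rate * conversion_coefficient
  if (raw) f else trunc_decimals(f, 0)
}

#' Grazing capacity in cow units
#'
#' `Cc = F / (I * D)`: standard dry forage (converted quintal -> kg) divided
#' by the daily intake of one cow unit times the grazing-season length,
#' rounded half-up to whole cow units.
#'
#' @param standard_forage_quintal standard dry forage F, quintal/year.
#' @param intake_kg_day daily dry-matter intake per cow unit, kg (default 7.5).
#' @param grazing_days grazing-season length in days (default 153,
#'   May-September).
#' @return capacity in cow units per year (integer).
#' @export
grazing_capacity <- function(standard_forage_quintal, intake_kg_day = 7.5,
                             grazing_days = 153) {
  validate_all(list(
    "standard forage must be >= 0" = all(standard_forage_quintal >= 0),
    "intake must be > 0" = intake_kg_day > 0,
    "grazing days must be > 0" = grazing_days > 0
  ))
  as.integer(round_half_up(standard_forage_quintal * 100 /
                             (intake_kg_day * grazing_days)))
}

#' Daily forage requirement of an animal
#'
#' An animal consumes 3 percent of its body weight as dry forage per day.
#'
#' @param body_weight_kg average body weight, kg.
#' @return dry-matter requirement in kg/day, at 2 decimals.
#' @export
forage_requirement <- function(body_weight_kg) {
  stopifnot(all(body_weight_kg > 0))
  round_half_up(0.03 * body_weight_kg, 2)
}

#' Convert a livestock census to cow units
#'
#' Multiplies head counts by the animal-unit (cow-equivalent) coefficient of
#' each animal type and totals per origin group (migratory/local), rounding
#' each group half-up to whole cow units. By default the printed animal-unit
#' column of the conversion table is used verbatim; `derive_au = TRUE`
#' recomputes AU as forage requirement / 7.5 instead (the two disagree
#' slightly for horses: 9.38/7.5 = 1.25 vs the tabulated 1.18).
#'
#' @param census data.frame with columns `year`, `animal`, `count`, `origin`.
#' @param au_table data.frame with columns `animal`, `body_weight_kg`,
#'   `forage_req_kg_day`, `animal_unit`; see [animal_unit_table()].
#' @param derive_au recompute AU from forage requirement (default FALSE).
#' @return list with `by_origin` (data.frame origin, cow_units), `total`
#'   (integer cow units) and `raw_total` (unrounded).
#' @export
to_cow_units <- function(census, au_table = animal_unit_table(),
                         derive_au = FALSE) {
  stopifnot(all(c("animal", "count", "origin") %in% names(census)),
            all(census$count >= 0))
  missing <- setdiff(unique(census$animal), au_table$animal)
  if (length(missing)) {
    stop("census animals missing from the animal-unit table: ",
         paste(missing, collapse = ", "))
  }
  au <- if (derive_au) au_table$forage_req_kg_day / 7.5 else au_table$animal_unit
  names(au) <- au_table$animal
  cu <- census$count * au[census$animal]
  by_origin_raw <- tapply(cu, census$origin, sum)
  by_origin <- data.frame(
    origin = names(by_origin_raw),
    cow_units = as.integer(round_half_up(as.numeric(by_origin_raw))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(by_origin = by_origin,
       total = sum(by_origin$cow_units),
       raw_total = sum(cu))
}

#' Surplus grazing pressure over capacity
#'
#' Cow units in excess of the grazing capacity, floored at zero when the herd
#' is under capacity.
#'
#' @param total_cu cow units grazing the area.
#' @param capacity grazing capacity in cow units.
#' @return deficit in cow units (>= 0).
#' @export
grazing_balance <- function(total_cu, capacity) {
  stopifnot(total_cu >= 0, capacity >= 0)
  max(0, total_cu - capacity)
}

#' Trend of cow-unit totals over years
#'
#' Ordinary least-squares slope of total cow units against calendar year.
#'
#' @param years integer vector of calendar years (>= 2 distinct values).
#' @param cu_totals cow-unit totals, same length.
#' @return list with `slope` (CU per year), `intercept`, and the fitted `lm`.
#' @export
cu_trend <- function(years, cu_totals) {
  if (length(years) < 2 || length(unique(years)) < 2) {
    stop("at least two distinct years are needed to fit a trend")
  }
  stopifnot(length(years) == length(cu_totals))
  fit <- stats::lm(cu_totals ~ years)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}

#' Full grazing assessment
#'
#' Chains per-species forage yields into standard forage, grazing capacity,
#' census cow units and the surplus to be controlled.
#'
#' @param species data.frame with columns `species`, `biomass_g_per_m2` and
#'   logical `palatable`; only palatable species enter the yield.
#' @param census livestock census (see [to_cow_units()]).
#' @param params list of grazing parameters; defaults from
#'   [default_config()]`$grazing`.
#' @param au_table animal-unit conversion table.
#' @return list with `total_yield`, `standard_forage`, `capacity`,
#'   `total_cu`, `deficit` and the per-species yield table.
#' @export
grazing_assessment <- function(species, census,
                               params = default_config()$grazing,
                               au_table = animal_unit_table()) {
  pal <- if ("palatable" %in% names(species)) {
    species[species$palatable, , drop = FALSE]
  } else species
  pal$forage_yield_quintal <- forage_yield(pal$biomass_g_per_m2,
                                           params$area_km2)
  total_yield <- sum(pal$forage_yield_quintal)
  f <- standard_forage(total_yield, params$utilization_rate,
                       params$conversion_coefficient)
  cc <- grazing_capacity(f, params$intake_kg_day, params$grazing_days)
  cu <- to_cow_units(census, au_table)
  list(
    species = pal,
    total_yield = total_yield,
    standard_forage = f,
    capacity = cc,
    total_cu = cu$total,
    cu_by_origin = cu$by_origin,
    deficit = grazing_balance(cu$total, cc)
  )
}
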