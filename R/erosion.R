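#' Sampling-core geometry
#'
#' The cylindrical iron core used for bulk-density sampling of check-dam
#' debris (default 2.5 cm radius, 30 cm height; volume pi r^2 h ~ 589 cm3).
#'
#' @param radius_cm core radius, cm.
#' @param height_cm core height, cm.
#' @return list with `radius_cm`, `height_cm`, `volume_cm3`.
#' @export
core_spec <- function(radius_cm = 2.5, height_cm = 30) {
  stopifnot(radius_cm > 0, height_cm > 0)
  list(radius_cm = radius_cm, height_cm = height_cm,
       volume_cm3 = pi * radius_cm^2 * height_cm)
}

#' Bulk density from a core sample
#'
#' Oven-dry mass of the soil extracted by the core divided by the core
#' volume.
#'
#' @param dry_mass_g oven-dry mass, g (vectorised over triplicates).
#' @param core a [core_spec()].
#' @return bulk density in g/cm3.
#' @export
core_density <- function(dry_mass_g, core = core_spec()) {
  stopifnot(all(dry_mass_g >= 0))
  if (core$volume_cm3 <= 0) stop("core volume must be positive")
  dry_mass_g / core$volume_cm3
}

#' Debris mass retained by one check dam
#'
#' `Md = V * mean(rho_b)`: stored debris volume times the mean of the
#' (typically triplicate) core bulk densities. Since 1 g/cm3 = 1 t/m3, a
#' volume in m3 times a density in g/cm3 is directly a mass in tonnes.
#'
#' @param volume_m3 stored debris volume, m3.
#' @param densities_g_cm3 one or more bulk-density measurements, g/cm3.
#' @return retained mass in tonnes.
#' @export
debris_mass <- function(volume_m3, densities_g_cm3) {
  if (length(densities_g_cm3) == 0) {
    stop("at least one bulk-density measurement is required")
  }
  stopifnot(all(volume_m3 >= 0), all(densities_g_cm3 >= 0))
  volume_m3 * mean(densities_g_cm3)
}

#' Erosion-control summary over a set of check dams
#'
#' Totals the debris mass retained per year over all dams and normalises by
#' the treated area to a t/ha/yr rate (reported at 1 decimal; the raw rate is
#' retained).
#'
#' @param dams data.frame with columns `dam`, `volume_m3` and one or more
#'   density columns `rho1`, `rho2`, ... (g/cm3); a `gully` column is carried
#'   as metadata.
#' @param area_ha treated area in hectares.
#' @return list `n_dams`, `total_mass_t` (2 decimals), `raw_total_mass_t`,
#'   `area_ha`, `rate_t_ha_yr` (1 decimal), `raw_rate`, `per_dam`.
#' @export
erosion_summary <- function(dams, area_ha) {
  stopifnot(area_ha > 0)
  if (is.null(dams) || nrow(dams) == 0) {
    warning("no check dams supplied; returning a zero summary")
    return(list(n_dams = 0L, total_mass_t = 0, raw_total_mass_t = 0,
                area_ha = area_ha, rate_t_ha_yr = 0, raw_rate = 0,
                per_dam = data.frame()))
  }
  rho_cols <- grep("^rho", names(dams), value = TRUE)
  if (!length(rho_cols)) stop("dams must carry density columns rho1, rho2, ...")
  md <- vapply(seq_len(nrow(dams)), function(i) {
    debris_mass(dams$volume_m3[i], as.numeric(dams[i, rho_cols]))
  }, numeric(1))
  per_dam <- data.frame(dam = dams$dam, mass_t = md,
                        stringsAsFactors = FALSE)
  if ("gully" %in% names(dams)) per_dam$gully <- dams$gully
  total <- sum(md)
  list(n_dams = nrow(dams),
       total_mass_t = round_half_up(total, 2),
       raw_total_mass_t = total,
       area_ha = area_ha,
       rate_t_ha_yr = round_half_up(total / area_ha, 1),
       raw_rate = total / area_ha,
       per_dam = per_dam)
}
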