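#' Survey design for quadrat sampling
#'
#' Describes the quadrat layout of one vegetation survey: the number of
#' quadrats pooled per zone and their area. Statistics pool all quadrats of a
#' zone; plot structure is metadata only.
#'
#' @param n_quadrats positive integer, quadrats laid per zone (default 30).
#' @param quadrat_area quadrat area in m2 (default 1).
#' @param quadrat_ids optional character vector of valid quadrat labels; when
#'   supplied, observations referencing other quadrats are rejected.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(n_quadrats = 30, quadrat_area = 1, quadrat_ids = NULL) {
  validate_all(list(
    "n_quadrats must be a positive integer" =
      length(n_quadrats) == 1 && n_quadrats >= 1 && n_quadrats == as.integer(n_quadrats),
    "quadrat_area must be > 0" = length(quadrat_area) == 1 && quadrat_area > 0,
    "quadrat_ids must match n_quadrats" =
      is.null(quadrat_ids) || length(unique(quadrat_ids)) == n_quadrats
  ))
  structure(
    list(n_quadrats = as.integer(n_quadrats), quadrat_area = quadrat_area,
         quadrat_ids = quadrat_ids),
    class = "survey_design"
  )
}

#' Per-species density, frequency and abundance from quadrat counts
#'
#' Pools all quadrats of one zone and computes, for every species observed:
#' density (individuals per m2: total individuals / total quadrats for 1 m2
#' quadrats), frequency (percent of quadrats occupied) and abundance
#' (individuals per occupied quadrat). Species absent from every quadrat are
#' omitted: their abundance is undefined. Empty quadrats are legal and count
#' in the denominator. Values are returned at full precision; use
#' [round_stats()] for 2-decimal presentation.
#'
#' @param observations data.frame with columns `zone`, `quadrat`, `species`,
#'   `count` (non-negative integers; a `plot` column is carried as metadata if
#'   present). All rows must belong to a single zone.
#' @param design a [survey_design()].
#' @return data.frame with one row per species present: `zone`, `species`,
#'   `density`, `frequency_pct`, `abundance`, `total_individuals`,
#'   `occupied_quadrats`.
#' @export
compute_species_stats <- function(observations, design = survey_design()) {
  stopifnot(inherits(design, "survey_design"))
  req <- c("zone", "quadrat", "species", "count")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(observations) == 0) {
    return(data.frame(zone = character(), species = character(),
                      density = numeric(), frequency_pct = numeric(),
                      abundance = numeric(), total_individuals = integer(),
                      occupied_quadrats = integer()))
  }
  validate_all(list(
    "all observations must belong to one zone" =
      length(unique(observations$zone)) == 1,
    "counts must be non-negative integers" =
      all(observations$count >= 0 & observations$count == round(observations$count)),
    "quadrat ids must belong to the design" =
      is.null(design$quadrat_ids) ||
        all(observations$quadrat %in% design$quadrat_ids),
    "observations cannot reference more quadrats than the design holds" =
      length(unique(observations$quadrat)) <= design$n_quadrats
  ))

  obs <- observations[observations$count > 0, , drop = FALSE]
  n <- design$n_quadrats
  area_total <- n * design$quadrat_area
  if (nrow(obs) == 0) {
    return(compute_species_stats(observations[0, , drop = FALSE], design))
  }

  total <- tapply(obs$count, obs$species, sum)
  occ <- tapply(obs$quadrat, obs$species, function(q) length(unique(q)))
  species <- names(total)
  out <- data.frame(
    zone = unique(observations$zone),
    species = species,
    density = as.numeric(total) / area_total,
    frequency_pct = 100 * as.numeric(occ) / n,
    abundance = as.numeric(total) / as.numeric(occ),
    total_individuals = as.integer(total),
    occupied_quadrats = as.integer(occ),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out[order(out$species), , drop = FALSE]
}

#' Zone-level vegetation summary
#'
#' Total herb density, species richness and the dominant community label of a
#' zone. The dominant community joins the `k` highest-density species names
#' with an em-dash, in descending density order; density ties break
#' alphabetically.
#'
#' @param stats per-species statistics as returned by
#'   [compute_species_stats()] (or a fixture with the same columns).
#' @param k number of species in the dominant-community label (default 4).
#' @return a one-row data.frame: `zone`, `total_herb_density`,
#'   `species_richness`, `dominant_community`.
#' @export
zone_summary <- function(stats, k = 4) {
  if (is.null(stats) || nrow(stats) == 0) {
    stop("no vegetation data: cannot summarise an empty species table")
  }
  stopifnot(k >= 1)
  ord <- order(-stats$density, stats$species)
  top <- stats$species[ord][seq_len(min(k, nrow(stats)))]
  data.frame(
    zone = unique(stats$zone)[1],
    total_herb_density = sum(stats$density),
    species_richness = nrow(stats),
    dominant_community = paste(top, collapse = "—"),
    stringsAsFactors = FALSE
  )
}

#' Round vegetation statistics for presentation
#'
#' Applies half-up rounding to the density, frequency and abundance columns.
#' Raw columns are preserved with a `_raw` suffix so full-precision values
#' remain available.
#'
#' @param stats data.frame from [compute_species_stats()].
#' @param decimals decimal places (default 2, the convention of printed
#'   vegetation tables).
#' @return the data.frame with rounded presentation columns.
#' @export
round_stats <- function(stats, decimals = 2) {
  stopifnot(decimals >= 0)
  for (col in c("density", "frequency_pct", "abundance")) {
    if (col %in% names(stats)) {
      stats[[paste0(col, "_raw")]] <- stats[[col]]
      stats[[col]] <- round_half_up(stats[[col]], decimals)
    }
  }
  stats
}
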