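#' Default scoring-criteria profile
#'
#' The threshold bands used to score the directly measured variables of the
#' restoration evaluation: soil chemistry (pH, organic carbon, N, P, K, water
#' holding capacity), vegetation cover, and the three management variables
#' (grazing cow units, daily tourists, erosion-control rate).
#'
#' Bands are encoded as one row per (variable, level, interval), with
#' inclusive bounds. Levels are checked in order satisfactory -> average ->
#' not_satisfactory, so a boundary shared by two bands resolves to the better
#' one (e.g. pH exactly 4.7 is satisfactory). Where the published bands leave
#' the upper side of a target band uncovered (pH above 5.3, water holding
#' capacity above 60), the profile mirrors the lower average bandwidth above
#' the satisfactory band and classes values beyond that as not satisfactory,
#' so every non-negative value is scoreable.
#'
#' @return data.frame with columns `variable`, `category`, `level`, `lower`,
#'   `upper`.
#' @export
default_criteria <- function() {
  path <- system.file("extdata", "scoring_criteria.csv", package = "bugyal")
  if (!nzchar(path)) path <- "inst/extdata/scoring_criteria.csv"
  load_criteria(path)
}

#' Load and validate a scoring-criteria profile
#'
#' Reads a band table from CSV and checks that every variable's bands cover
#' all non-negative values without leaving gaps between the stated intervals'
#' union (totality is checked on a dense grid of the [0, 1000] range scaled
#' to each variable's span plus the unbounded tails).
#'
#' @param path CSV with columns `variable`, `category`, `level`, `lower`,
#'   `upper` (empty cells mean unbounded).
#' @return validated criteria data.frame.
#' @export
load_criteria <- function(path) {
  cr <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("variable", "category", "level", "lower", "upper")
  if (!all(req %in% names(cr))) {
    stop("criteria file must have columns: ", paste(req, collapse = ", "))
  }
  cr$lower <- ifelse(is.na(cr$lower), -Inf, as.numeric(cr$lower))
  cr$upper <- ifelse(is.na(cr$upper), Inf, as.numeric(cr$upper))
  bad_level <- setdiff(unique(cr$level),
                       c("satisfactory", "average", "not_satisfactory"))
  if (length(bad_level)) stop("unknown levels: ", paste(bad_level, collapse = ", "))
  if (any(cr$lower > cr$upper)) stop("criteria bands with lower > upper")
  # totality over non-negative values, probed on a grid spanning each variable
  for (v in unique(cr$variable)) {
    b <- cr[cr$variable == v, ]
    hi <- max(b$upper[is.finite(b$upper)], 1)
    probes <- unique(c(0, b$lower[is.finite(b$lower)],
                       b$upper[is.finite(b$upper)],
                       seq(0, hi * 1.5, length.out = 200)))
    covered <- vapply(probes, function(x) any(x >= b$lower & x <= b$upper),
                      logical(1))
    if (!all(covered)) {
      stop("criteria for '", v, "' leave values uncovered, e.g. ",
           signif(probes[!covered][1], 4))
    }
  }
  cr
}
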