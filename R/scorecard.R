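#' Score one variable against its threshold bands
#'
#' Assigns a level (satisfactory / average / not satisfactory) by matching the
#' measured value against the variable's bands, levels checked best-first so
#' shared boundaries fall to the better band, and maps the level to a numeric
#' score: satisfactory 3, average `mid_score` (default 1.5, the midpoint of
#' the 0-3 scale), not satisfactory 0.
#'
#' @param value measured value of the variable.
#' @param variable variable name, matching the criteria profile.
#' @param criteria band table from [default_criteria()] or [load_criteria()].
#' @param mid_score numeric score for the "average" level (default 1.5).
#' @return list `variable`, `raw_value`, `level`, `score`, `category`.
#' @export
score_variable <- function(value, variable, criteria = default_criteria(),
                           mid_score = 1.5) {
  stopifnot(is.numeric(value), length(value) == 1,
            mid_score >= 0, mid_score <= 3)
  b <- criteria[criteria$variable == variable, , drop = FALSE]
  if (nrow(b) == 0) stop("no scoring bands defined for variable '", variable, "'")
  level <- NA_character_
  for (lv in c("satisfactory", "average", "not_satisfactory")) {
    bb <- b[b$level == lv, , drop = FALSE]
    if (nrow(bb) && any(value >= bb$lower & value <= bb$upper)) {
      level <- lv
      break
    }
  }
  if (is.na(level)) {
    stop("value ", value, " for '", variable,
         "' falls outside every defined band")
  }
  score <- c(satisfactory = 3, average = mid_score, not_satisfactory = 0)[[level]]
  list(variable = variable, raw_value = value, level = level, score = score,
       category = b$category[1])
}

#' Category index from variable scores
#'
#' Sum of the variable scores divided by the maximum attainable
#' (3 x number of variables); lies in [0, 1].
#'
#' @param scores numeric vector of variable scores in [0, 3], or a list of
#'   results from [score_variable()].
#' @return list `index` (in [0, 1]), `raw_sum`, `n_variables`.
#' @export
category_index <- function(scores) {
  if (is.list(scores) && !is.numeric(scores)) {
    scores <- vapply(scores, function(s) s$score, numeric(1))
  }
  if (length(scores) == 0) stop("cannot compute a category index without scores")
  stopifnot(all(scores >= 0 & scores <= 3))
  list(index = sum(scores) / (3 * length(scores)),
       raw_sum = sum(scores),
       n_variables = length(scores))
}

#' Restoration evaluation index
#'
#' Sum of the raw category score sums divided by the maximum possible score
#' and expressed as a percentage, clamped to [0, 100]. The published scoring
#' scheme divides by a stated maximum of 16; this is kept as a configurable
#' constant since it is not derivable from the category structure.
#'
#' @param raw_scores numeric vector of raw category score sums.
#' @param max_score maximum possible score (default 16).
#' @return percent value in [0, 100].
#' @export
evaluation_index <- function(raw_scores, max_score = 16) {
  stopifnot(max_score > 0, all(raw_scores >= 0))
  min(100, max(0, sum(raw_scores) / max_score * 100))
}

#' Aggregate socio-economic survey ratings
#'
#' Maps the three-level performance ratings low/moderate/high to 0 / 1.5 / 3
#' and averages per variable across respondents; also tabulates rating
#' proportions per village and per age group.
#'
#' @param responses data.frame with columns `respondent`, `village`,
#'   `age_group`, `variable`, `rating` (values "L", "M", "H").
#' @param rating_scores named numeric vector mapping ratings to scores.
#' @return list `variable_scores` (data.frame variable, score, n),
#'   `by_village`, `by_age_group` (rating proportion tables).
#' @export
aggregate_survey <- function(responses,
                             rating_scores = c(L = 0, M = 1.5, H = 3)) {
  req <- c("respondent", "village", "age_group", "variable", "rating")
  stopifnot(all(req %in% names(responses)))
  bad <- setdiff(unique(responses$rating), names(rating_scores))
  if (length(bad)) stop("unknown ratings: ", paste(bad, collapse = ", "))
  if (nrow(responses) == 0) stop("no survey responses to aggregate")
  sc <- rating_scores[responses$rating]
  agg <- tapply(sc, responses$variable, mean)
  n <- tapply(sc, responses$variable, length)
  variable_scores <- data.frame(variable = names(agg),
                                score = as.numeric(agg),
                                n = as.integer(n),
                                row.names = NULL, stringsAsFactors = FALSE)
  list(
    variable_scores = variable_scores,
    by_village = prop.table(table(responses$village, responses$rating), 1),
    by_age_group = prop.table(table(responses$age_group, responses$rating), 1)
  )
}

#' Ecosystem index score of a zone
#'
#' Scores the directly measured (management + environmental) variables of
#' each replicate against the criteria profile, converts each replicate to a
#' percent of the maximum (sum of scores / (3 x n variables) x 100), and
#' reports the zone mean with its standard error.
#'
#' @param zone_values data.frame with columns `replicate`, `variable`,
#'   `value`; every replicate must carry every variable.
#' @param zone zone label.
#' @param criteria band table.
#' @param mid_score score of the "average" level.
#' @return list `zone`, `mean`, `se`, `replicate_scores` (percent per
#'   replicate), `n_variables`.
#' @export
ecosystem_index <- function(zone_values, zone = "zone",
                            criteria = default_criteria(), mid_score = 1.5) {
  stopifnot(all(c("replicate", "variable", "value") %in% names(zone_values)))
  vars <- unique(zone_values$variable)
  reps <- unique(zone_values$replicate)
  pct <- vapply(reps, function(r) {
    sub <- zone_values[zone_values$replicate == r, , drop = FALSE]
    missing <- setdiff(vars, sub$variable)
    if (length(missing)) {
      stop("replicate '", r, "' is missing variables: ",
           paste(missing, collapse = ", "))
    }
    s <- vapply(seq_len(nrow(sub)), function(i) {
      score_variable(sub$value[i], sub$variable[i], criteria, mid_score)$score
    }, numeric(1))
    sum(s) / (3 * nrow(sub)) * 100
  }, numeric(1))
  se <- if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else NA_real_
  list(zone = zone, mean = mean(pct), se = se,
       replicate_scores = unname(pct), n_variables = length(vars))
}

#' Rank zones by ecosystem index
#'
#' Orders zone scores descending by mean; exact ties keep input order and are
#' flagged. No hypothesis testing is performed.
#'
#' @param scores list of results from [ecosystem_index()].
#' @return data.frame `zone`, `mean`, `se`, `rank`, `tied`.
#' @export
rank_zones <- function(scores) {
  if (length(scores) < 2) stop("need at least two zones to rank")
  df <- data.frame(
    zone = vapply(scores, `[[`, character(1), "zone"),
    mean = vapply(scores, `[[`, numeric(1), "mean"),
    se = vapply(scores, function(s) s$se %||% NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$mean)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$tied <- duplicated(df$mean) | duplicated(df$mean, fromLast = TRUE)
  rownames(df) <- NULL
  df
}
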