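test_that("variables score against their threshold bands", {
  cases <- list(
    list(v = 4.96,  var = "pH",              level = "satisfactory", score = 3),
    list(v = 49.85, var = "WHC",             level = "average",      score = 1.5),
    list(v = 0.5,   var = "erosion_control", level = "satisfactory", score = 3),
    list(v = 881,   var = "grazing_control", level = "not_satisfactory", score = 0),
    list(v = 54,    var = "tourist_control", level = "satisfactory", score = 3),
    list(v = 3.76,  var = "OC",              level = "not_satisfactory", score = 0)
  )
  for (cs in cases) {
    s <- score_variable(cs$v, cs$var)
    expect_equal(s$level, cs$level, info = cs$var)
    expect_equal(s$score, cs$score, info = cs$var)
  }
  expect_error(score_variable(1, "unknown_variable"), "no scoring bands")
})

test_that("band boundaries resolve to the better band", {
  expect_equal(score_variable(4.7, "pH")$level, "satisfactory")
  expect_equal(score_variable(5.3, "pH")$level, "satisfactory")
  expect_equal(score_variable(4.0, "pH")$level, "average")
  expect_equal(score_variable(50, "WHC")$level, "satisfactory")
  expect_equal(score_variable(40, "WHC")$level, "average")
  expect_equal(score_variable(285, "grazing_control")$level, "satisfactory")
})

test_that("the shipped criteria profile covers all non-negative values", {
  cr <- default_criteria()
  grid <- c(seq(0, 14, by = 0.05), seq(0, 100, by = 0.5), seq(0, 2000, by = 5))
  for (v in unique(cr$variable)) {
    for (x in sample(grid, 80)) {
      expect_silent(score_variable(x, v, cr))
    }
  }
  # an incomplete user profile errors on the gap
  gap <- cr[!(cr$variable == "pH" & cr$level == "average"), ]
  expect_error(score_variable(4.2, "pH", gap), "outside every defined band")
})

test_that("category index averages scores on the 0-1 scale", {
  ci <- category_index(c(3, 3, 1.5))
  expect_equal(round(ci$index, 2), 0.83)
  expect_equal(ci$raw_sum, 7.5)
  expect_equal(category_index(rep(3, 5))$index, 1)
  expect_equal(category_index(rep(0, 4))$index, 0)
  expect_error(category_index(numeric(0)), "without scores")
})

test_that("evaluation index normalises raw category sums to percent", {
  # consistency fixture: a raw sum of 11.09 over a 16-point maximum
  expect_equal(evaluation_index(11.09, 16), 69.3125)
  expect_equal(round(evaluation_index(11.09), 2), 69.31)
  expect_equal(evaluation_index(0), 0)
  expect_equal(evaluation_index(16), 100)
  expect_equal(evaluation_index(20, 16), 100)   # clamped
})

test_that("improving a raw value toward its satisfactory band never lowers scores", {
  cr <- default_criteria()
  # higher-better, lower-better and target-band variables
  for (case in list(list(var = "OC", seq = c(2, 5, 6, 7.5, 9)),
                    list(var = "grazing_control", seq = c(900, 857, 400, 285, 100)),
                    list(var = "pH", seq = c(3.5, 4.2, 4.7, 5.0)))) {
    s <- vapply(case$seq, function(x) score_variable(x, case$var, cr)$score,
                numeric(1))
    expect_true(all(diff(s) >= 0), info = case$var)
  }
})

test_that("survey aggregation maps L/M/H to the 0-3 scale", {
  resp <- function(ratings) {
    data.frame(respondent = paste0("R", seq_along(ratings)), village = "Barsu",
               age_group = "20-40", variable = "social_preference",
               rating = ratings, stringsAsFactors = FALSE)
  }
  expect_equal(aggregate_survey(resp(rep("H", 10)))$variable_scores$score, 3)
  expect_equal(aggregate_survey(resp(c("L", "H")))$variable_scores$score, 1.5)
  expect_error(aggregate_survey(resp("X")), "unknown ratings")
  # multinomial oracle: mean score 0.1*0 + 0.3*1.5 + 0.6*3 = 2.25
  sv <- gen_survey(c(L = 0.1, M = 0.3, H = 0.6), n_respondents = 30, seed = 9)
  agg <- aggregate_survey(sv)
  expect_true(all(abs(agg$variable_scores$score - 2.25) < 0.45))
  expect_lt(abs(mean(agg$variable_scores$score) - 2.25), 0.25)
})

test_that("ecosystem index scores replicates and reports mean with SE", {
  vals <- data.frame(
    replicate = rep(1:2, each = 3),
    variable = rep(c("pH", "WHC", "OC"), 2),
    value = c(5.0, 55, 8.0,    # all satisfactory -> 100%
              5.0, 45, 8.0)    # one average      -> (3+1.5+3)/9
  )
  ei <- ecosystem_index(vals, zone = "T")
  expect_equal(ei$replicate_scores[1], 100)
  expect_equal(ei$replicate_scores[2], 7.5 / 9 * 100)
  expect_equal(ei$mean, mean(ei$replicate_scores))
  expect_equal(ei$se, sd(ei$replicate_scores) / sqrt(2))
  missing <- vals[-2, ]
  expect_error(ecosystem_index(missing), "missing variables")
})

test_that("zones rank by mean score with reference above treated above degraded", {
  mk <- function(zone, m) list(zone = zone, mean = m, se = 1,
                               replicate_scores = m, n_variables = 6)
  r <- rank_zones(list(mk("treated", 72), mk("reference", 88),
                       mk("degraded", 55.61)))
  expect_equal(r$zone, c("reference", "treated", "degraded"))
  expect_false(any(r$tied))
  tie <- rank_zones(list(mk("a", 10), mk("b", 10)))
  expect_true(all(tie$tied))
  expect_error(rank_zones(list(mk("a", 1))), "at least two")

  # on soil chemistry generated around the published zone means, the
  # ecosystem index preserves the zone ordering
  soil <- gen_soil(soil_zone_table(), n_replicates = 3, seed = 4)
  cr <- default_criteria()
  scoreable <- intersect(unique(soil$variable), unique(cr$variable))
  zones <- lapply(c("R", "GTZ", "UTZ"), function(z) {
    zv <- soil[soil$zone == z & soil$variable %in% scoreable,
               c("replicate", "variable", "value")]
    ecosystem_index(zv, zone = z, criteria = cr)
  })
  rk <- rank_zones(zones)
  expect_equal(rk$zone, c("R", "GTZ", "UTZ"))
  expect_true(all(rk$mean >= 0 & rk$mean <= 100))
})

test_that("all indices stay bounded on random inputs", {
  set.seed(42)
  cr <- default_criteria()
  vars <- unique(cr$variable)
  for (i in 1:50) {
    v <- sample(vars, 1)
    hi <- max(cr$upper[cr$variable == v & is.finite(cr$upper)], 10)
    s <- score_variable(runif(1, 0, hi * 1.4), v, cr)
    expect_true(s$score >= 0 && s$score <= 3)
  }
  for (i in 1:20) {
    sc <- runif(sample(1:8, 1), 0, 3)
    expect_true(category_index(sc)$index >= 0 && category_index(sc)$index <= 1)
    ev <- evaluation_index(runif(3, 0, 8))
    expect_true(ev >= 0 && ev <= 100)
  }
})
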