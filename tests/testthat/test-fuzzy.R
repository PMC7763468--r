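gastro <- read_disease_config(gastro_config_path())

test_that("trapezoidal membership covers plateau, ramps and degenerate corners", {
  tz <- fuzzy_trapezoid("t", 0, 2, 4, 8)
  expect_equal(trapezoid_membership(3, tz), 1)          # plateau center
  expect_equal(trapezoid_membership(0, tz), 0)          # lower corner
  expect_equal(trapezoid_membership(1, tz), 0.5)        # rising ramp midpoint
  expect_equal(trapezoid_membership(6, tz), 0.5)        # falling ramp midpoint
  expect_equal(trapezoid_membership(c(-1, 9), tz), c(0, 0))
  # crisp spike
  spike <- fuzzy_trapezoid("s", 5, 5, 5, 5)
  expect_equal(trapezoid_membership(c(5, 4.999, 5.001), spike), c(1, 0, 0))
  # open shoulder
  sh <- fuzzy_trapezoid("a-", -Inf, -Inf, 10, 20)
  expect_equal(trapezoid_membership(c(-1e6, 10, 15, 20), sh), c(1, 1, 0.5, 0))
  expect_error(fuzzy_trapezoid("bad", 4, 2, 1, 0))
})

test_that("fuzzification reproduces the calibrated reference degrees", {
  # leaving-home duration 4600 s
  f <- fuzzify_variable(4600, gastro$variables[["leaving_home.duration"]])
  expect_equal(unname(f["Abnormal-"]), 0.3)
  expect_equal(unname(f["Normal"]), 0.1)
  # sleeping duration 30,000 s
  f <- fuzzify_variable(30000, gastro$variables[["sleeping.duration"]])
  expect_equal(unname(f["Abnormal-"]), 0.2)
  expect_equal(unname(f["Normal"]), 0.6)
  # a value at the Normal plateau center is fully normal
  f <- fuzzify_variable(36000, gastro$variables[["sleeping.duration"]])
  expect_equal(unname(f), c(0, 1, 0))
  # boundary values of the normal range stay Normal with degree 1
  f <- fuzzify_variable(2, gastro$variables[["leaving_home.frequency"]])
  expect_equal(unname(f["Normal"]), 1)
})

test_that("rule evaluation is min over AND groups and max within OR groups", {
  fz <- list(a = c("Abnormal-" = 0.3, Normal = 0.7, "Abnormal+" = 0),
             b = c("Abnormal-" = 0.2, Normal = 1, "Abnormal+" = 0))
  and_rule <- list(consequent = "Low", groups = list(
    data.frame(variable = "a", subset = "Abnormal-"),
    data.frame(variable = "b", subset = "Normal")))
  expect_equal(evaluate_rule(and_rule, fz), 0.3)   # min(0.3, 1)
  or_rule <- list(consequent = "High", groups = list(
    data.frame(variable = c("a", "b"), subset = c("Abnormal-", "Normal"))))
  expect_equal(evaluate_rule(or_rule, fz), 1)      # max(0.3, 1)
  mixed <- list(consequent = "High", groups = list(
    data.frame(variable = c("a", "b"), subset = c("Abnormal-", "Abnormal-"))))
  expect_equal(evaluate_rule(mixed, fz), 0.3)      # max(0.3, 0.2)
  zero <- list(consequent = "Low", groups = list(
    data.frame(variable = "a", subset = "Abnormal+"),
    data.frame(variable = "b", subset = "Normal")))
  expect_equal(evaluate_rule(zero, fz), 0)         # AND absorbs a zero clause
  bad <- list(consequent = "Low", groups = list(
    data.frame(variable = "zz", subset = "Normal")))
  expect_error(evaluate_rule(bad, fz), "unknown variable")
})

test_that("inference clips consequents and aggregates by pointwise max", {
  out <- gastro$output_sets
  full <- mamdani_infer(c(Low = 1), out, 1001)
  expect_equal(full$mu, trapezoid_membership(full$y, out$Low))
  # two rules into the same set clip at the larger activation
  two <- mamdani_infer(c(Low = 0.3), out, 1001)
  both <- local({
    a <- pmin(0.3, trapezoid_membership(two$y, out$Low))
    b <- pmin(0.1, trapezoid_membership(two$y, out$Low))
    pmax(a, b)
  })
  expect_equal(two$mu, both)
  expect_equal(max(two$mu), 0.3)
  none <- mamdani_infer(c(Low = 0, High = 0), out, 101)
  expect_false(none$fired)
  expect_equal(sum(none$mu), 0)
})

test_that("centroid defuzzification matches symmetry, hand values and quadrature", {
  # symmetric membership about 0.5
  y <- seq(0, 1, length.out = 1001)
  mu <- trapezoid_membership(y, fuzzy_trapezoid("m", 0.2, 0.4, 0.6, 0.8))
  expect_equal(defuzzify_centroid(y, mu), 0.5, tolerance = 1e-9)
  # discrete two-sample case: (0.2*1 + 0.8*3) / (1 + 3)
  expect_equal(defuzzify_centroid(c(0.2, 0.8), c(1, 3)), 0.65)
  # Low set clipped at 0.3 vs fine-grid quadrature
  clip_fn <- function(v) pmin(0.3, trapezoid_membership(v, gastro$output_sets$Low))
  agg <- mamdani_infer(c(Low = 0.3), gastro$output_sets, gastro$grid_n)
  expect_lt(abs(defuzzify_centroid(agg$y, agg$mu) - quadrature_centroid(clip_fn)),
            1e-3)
  expect_error(defuzzify_centroid(y, numeric(length(y))), "no assessment")
})

worked_observation <- c(
  "leaving_home.duration" = 4600, "going_to_toilet.duration" = 2880,
  "eating.duration" = 3720, "sleeping.duration" = 32400,
  "leaving_home.frequency" = 2, "going_to_toilet.frequency" = 12,
  "eating.frequency" = 3, "sleeping.frequency" = 2)

test_that("the worked deviation day assesses Low with a Minor alert", {
  a <- assess_disease_day(worked_observation, gastro, day_index = 1)
  # AND over the eight conditions: min(0.3, 1, ...) = 0.3 into Low
  expect_equal(unname(a$activations["Low"]), 0.3)
  expect_equal(unname(a$activations["High"]), 0)
  expect_equal(unname(a$activations["Very high"]), 0)
  expect_equal(a$category, "Low")
  expect_equal(a$alert, "Minor")
  expect_equal(a$n_abnormal_states, 1L)
  # calibration target for the shipped corners
  expect_lt(abs(a$level - 0.19), 0.02)
  # level stays inside the support of the aggregated set
  expect_lt(a$level, 0.4)
})

deep_observation <- function(abnormal_ids) {
  obs <- vapply(gastro$variables, function(v) (v$normal_min + v$normal_max) / 2,
                numeric(1))
  names(obs) <- names(gastro$variables)
  for (id in abnormal_ids) {
    v <- gastro$variables[[id]]
    obs[id] <- v$normal_min - 10 * (v$normal_max - v$normal_min) - 10000
  }
  obs
}

test_that("abnormal-state counts drive the illness level as configured", {
  ids <- names(gastro$variables)
  a0 <- assess_disease_day(deep_observation(character(0)), gastro)
  expect_equal(a0$category, "Low")
  a1 <- assess_disease_day(deep_observation(ids[1]), gastro)
  expect_equal(a1$category, "Low")
  a2 <- assess_disease_day(deep_observation(ids[1:2]), gastro)
  expect_equal(a2$category, "High")
  a3 <- assess_disease_day(deep_observation(ids[1:3]), gastro)
  expect_equal(a3$category, "High")
  a4 <- assess_disease_day(deep_observation(ids[1:4]), gastro)
  expect_equal(a4$category, "Very high")
  a8 <- assess_disease_day(deep_observation(ids), gastro)
  expect_equal(a8$category, "Very high")
  expect_equal(a8$alert, "Major")
  levels <- c(a0$level, a1$level, a2$level, a3$level, a4$level, a8$level)
  expect_true(all(diff(levels) >= -1e-9))
})

test_that("pushing any input further out of range never lowers the level", {
  ids <- names(gastro$variables)
  base <- deep_observation(ids[c(1, 5)])
  a_base <- assess_disease_day(base, gastro)$level
  for (id in ids) {
    v <- gastro$variables[[id]]
    for (step in c(0.1, 0.5, 2, 20)) {
      obs <- base
      obs[id] <- min(obs[id], v$normal_min - step * (v$normal_max - v$normal_min + 1))
      lvl <- assess_disease_day(obs, gastro)$level
      expect_gte(lvl + 1e-9, a_base)
      a_base_id <- lvl  # levels must be monotone along the sweep too
    }
  }
})

test_that("an escalating then recovering episode traces the expected level arc", {
  ids <- names(gastro$variables)
  counts <- c(1, 1, 2, 3, 4, 5, 4, 3, 2, 1)
  assessments <- lapply(seq_along(counts), function(i) {
    assess_disease_day(deep_observation(ids[seq_len(counts[i])]), gastro,
                       day_index = i)
  })
  levels <- vapply(assessments, `[[`, numeric(1), "level")
  cats <- vapply(assessments, `[[`, character(1), "category")
  peak <- which.max(levels)
  expect_true(peak > 1 && peak < length(levels))
  expect_true(all(diff(levels[1:peak]) >= -1e-9))
  expect_true(all(diff(levels[peak:length(levels)]) <= 1e-9))
  expect_equal(cats[1], "Low")
  expect_equal(cats[length(cats)], "Low")
  expect_true("Very high" %in% cats[peak])
  expect_true(all(cats %in% c("Low", "High", "Very high")))
})
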