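pattern_row <- function(start, duration) {
  data.frame(usual_start = start, usual_duration = duration)
}

test_that("similarity is the temporal intersection over the normal duration", {
  pat <- pattern_row(43200, 17 * 60)
  # identical interval: full overlap
  expect_equal(similarity_score(43200, 17 * 60, pat), 100)
  # normal 12:00-12:17, observed 12:11-12:32 -> intersection 6 of 17 min
  expect_equal(round_half_up(similarity_score(43200 + 11 * 60, 21 * 60, pat)),
               35.29)
  # disjoint intervals clamp to 0 instead of going negative
  expect_equal(similarity_score(50000, 600, pat), 0)
  expect_error(similarity_score(0, 60, pattern_row(0, 0)), "duration")
})

test_that("duration score is the observed share of the normal duration", {
  pat <- pattern_row(43200, 17 * 60)
  expect_equal(duration_score(17 * 60, pat), 100)
  expect_equal(round_half_up(duration_score(21 * 60, pat)), 123.53)
  expect_equal(duration_score(30 * 60, pattern_row(0, 60 * 60)), 50)
})

test_that("similarity agrees with a brute-force grid overlap counter", {
  set.seed(15)
  for (i in 1:50) {
    s_pat <- sample(30000:50000, 1); d_pat <- sample(300:7200, 1)
    s_obs <- s_pat + sample(-3600:3600, 1); d_obs <- sample(300:7200, 1)
    got <- similarity_score(s_obs, d_obs, pattern_row(s_pat, d_pat))
    want <- grid_overlap_pct(s_obs, d_obs, s_pat, d_pat, unit = 1)
    expect_lt(abs(got - want), 100 / d_pat + 1e-9)  # within one grid unit
  }
})

test_that("similarity is 100 exactly when the pattern interval is covered", {
  pat <- pattern_row(40000, 1200)
  expect_equal(similarity_score(39000, 3000, pat), 100)   # superset
  expect_lt(similarity_score(40001, 1200, pat), 100)      # 1 s shaved
  expect_lt(similarity_score(39000, 2199, pat), 100)
})

scoring_profile <- function() {
  sim <- make_sim(seed = 4, days = 30)
  build_normal_behavior(sim$truth, n_days = 30)
}

test_that("a day matching the routine scores 100/100 and misses drop the mean", {
  prof <- scoring_profile()
  p <- prof$patterns
  ideal <- activity_instances(
    ifelse(startsWith(p$label, "eating"), "eating", p$label),
    rep(1L, nrow(p)), p$usual_start, p$usual_duration)
  sc <- daily_scores(ideal, prof)
  expect_equal(sc$similarity_pct, 100)
  expect_equal(sc$duration_pct, 100)
  # drop one of the expected activities: its similarity contributes 0
  n <- nrow(p)
  drop_one <- ideal[ideal$label != "taking_shower", ]
  sc2 <- daily_scores(drop_one, prof)
  expect_equal(sc2$similarity_pct, 100 * (n - 1) / n)
  expect_false("taking_shower" %in% names(sc2$duration_pct_by_activity))
})

test_that("several instances of one activity average within the activity first", {
  prof <- scoring_profile()
  lunch <- prof$patterns[prof$patterns$label == "eating_lunch", ]
  others <- prof$patterns[prof$patterns$label != "eating_lunch", ]
  inst <- activity_instances(
    c(ifelse(startsWith(others$label, "eating"), "eating", others$label),
      "eating", "eating"),
    rep(1L, nrow(others) + 2),
    c(others$usual_start, lunch$usual_start, lunch$usual_start + 120),
    c(others$usual_duration, lunch$usual_duration * 0.8,
      lunch$usual_duration * 0.6))
  sc <- daily_scores(inst, prof)
  expect_equal(unname(sc$duration_pct_by_activity["eating_lunch"]), 70)
})

test_that("daily similarity never increases when one activity's overlap shrinks", {
  prof <- scoring_profile()
  p <- prof$patterns
  base <- activity_instances(
    ifelse(startsWith(p$label, "eating"), "eating", p$label),
    rep(1L, nrow(p)), p$usual_start, p$usual_duration)
  prev <- daily_scores(base, prof)$similarity_pct
  shower <- which(base$label == "taking_shower")
  for (shift in c(120, 300, 600, 1800, 3600)) {
    shifted <- base
    shifted$start[shower] <- shifted$start[shower] + shift
    shifted$end[shower] <- shifted$start[shower] + shifted$duration[shower]
    cur <- daily_scores(shifted, prof)$similarity_pct
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("frequency flags use inclusive range boundaries", {
  tp <- structure(list(slot_hours = 2L, slot_min = rep(0L, 12),
                       slot_max = rep(2L, 12), daily_count_range = c(10, 12),
                       max_duration_range = c(200, 400),
                       total_duration_range = c(2000, 4000)),
                  class = "toilet_profile")
  day_with <- function(k) activity_instances(
    rep("going_to_toilet", k), rep(1L, k),
    seq(30000, by = 3600, length.out = k), rep(240, k))
  expect_equal(frequency_flags(day_with(12), tp)$daily_flag, "Normal")
  expect_equal(frequency_flags(day_with(10), tp)$daily_flag, "Normal")
  expect_equal(frequency_flags(day_with(15), tp)$daily_flag, "Abnormal+")
  expect_equal(frequency_flags(day_with(9), tp)$daily_flag, "Abnormal-")
  expect_equal(range_flag(c(9, 10, 11, 12, 13), c(10, 12)),
               c("Abnormal-", "Normal", "Normal", "Normal", "Abnormal+"))
})
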