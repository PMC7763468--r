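make_lunches <- function(n = 30, outlier = TRUE, seed = 5) {
  set.seed(seed)
  start <- round(rnorm(n, 44100, 600))          # ~12:15 +- 10 min
  dur <- round(rnorm(n, 2100, 300))             # ~35 +- 5 min
  if (outlier) { start <- c(start, 44100); dur <- c(dur, 7200) }
  activity_instances(rep("eating", length(start)), seq_along(start), start, dur)
}

test_that("noise is excluded from pattern means and ranges", {
  inst <- make_lunches()
  pats <- build_activity_patterns(inst, profiling_config(), n_days = 31)
  expect_equal(nrow(pats), 1)
  expect_lt(pats$dur_max, 7200)                 # the 120-min outlier is out
  expect_lt(abs(pats$usual_duration - 2100), 3 * 300 / sqrt(30))
  expect_lt(abs(pats$usual_start - 44100), 3 * 600 / sqrt(30))
  # with the outlier kept in, the mean would shift: guards noise elimination
  naive_mean <- mean(inst$duration)
  expect_gt(abs(naive_mean - 2100), abs(pats$usual_duration - 2100))
})

test_that("meals drawn in three daily windows give three patterns", {
  set.seed(9)
  days <- rep(1:30, each = 3)
  start <- round(rnorm(90, rep(c(35040, 45000, 68400), 30), 300))
  dur <- round(rnorm(90, 1400, 120))
  inst <- activity_instances(rep("eating", 90), days, start, dur)
  pats <- build_activity_patterns(inst, profiling_config(), n_days = 30)
  expect_equal(nrow(pats), 3)
  expect_equal(sort(adlmonitor:::name_meal_patterns(pats)$label),
               c("eating_breakfast", "eating_dinner", "eating_lunch"))
})

test_that("identical repeated instances yield the instance itself as pattern", {
  inst <- activity_instances(rep("taking_shower", 10), 1:10,
                             rep(63000, 10), rep(900, 10))
  pats <- build_activity_patterns(inst, profiling_config(), n_days = 10)
  expect_equal(pats$usual_start, 63000)
  expect_equal(pats$usual_duration, 900)
  expect_equal(c(pats$dur_min, pats$dur_max), c(900, 900))
  expect_equal(c(pats$freq_min, pats$freq_max), c(1, 1))
})

test_that("all-noise input returns an empty pattern list with a warning", {
  inst <- activity_instances(rep("eating", 3), 1:3, c(1000, 40000, 80000),
                             c(600, 1200, 1800))
  expect_warning(pats <- build_activity_patterns(inst, profiling_config(),
                                                 n_days = 3),
                 "noise")
  expect_equal(nrow(pats), 0)
})

test_that("toilet profile summarizes slots, daily counts and durations", {
  # constructed baseline: 10-12 visits/day
  set.seed(3)
  rows <- lapply(1:20, function(d) {
    k <- sample(10:12, 1)
    activity_instances(rep("going_to_toilet", k), rep(d, k),
                       sort(sample(seq(21600, 82800, by = 900), k)),
                       rep(240, k))
  })
  inst <- do.call(rbind, rows)
  prof <- build_toilet_profile(inst, slot_hours = 2, n_days = 20)
  expect_equal(prof$daily_count_range, c(10, 12))
  expect_length(prof$slot_min, 12)
  expect_equal(prof$max_duration_range, c(240, 240))
  # empty input: all-zero profile
  empty <- build_toilet_profile(activity_instances(), slot_hours = 2)
  expect_equal(empty$daily_count_range, c(0, 0))
  expect_equal(sum(empty$slot_max), 0)
  # slot arithmetic
  expect_length(build_toilet_profile(inst, slot_hours = 4, n_days = 20)$slot_min, 6)
  expect_error(build_toilet_profile(inst, slot_hours = 5), "24")
})

test_that("a housebound baseline simply omits the leaving-home pattern", {
  sim <- make_sim(seed = 3, days = 12)
  inst <- sim$truth[sim$truth$label != "leaving_home", ]
  expect_warning(prof <- build_normal_behavior(inst, n_days = 12),
                 "leaving_home")
  expect_false("leaving_home" %in% prof$patterns$label)
  expect_gt(nrow(prof$patterns), 0)
})

test_that("profiling a clean baseline recovers the generator parameters", {
  spec <- routine_spec(days = 30, seed = 1)
  hits <- 0L
  for (s in 1:5) {
    sim <- generate_routine_log(routine_spec(days = 30, seed = s))
    prof <- build_normal_behavior(sim$truth, n_days = 30)
    acts <- spec$activities
    ok <- TRUE
    for (i in seq_len(nrow(acts))) {
      pat <- prof$patterns[abs(prof$patterns$usual_start - acts$start_mean[i]) < 3600, ]
      if (nrow(pat) != 1) { ok <- FALSE; next }
      se <- acts$duration_sd[i] / sqrt(30)
      if (abs(pat$usual_duration - acts$duration_mean[i]) >= 3 * se) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits, 4)   # full 20-seed recovery check lives in the acceptance suite
})

test_that("profiles round-trip through JSON", {
  sim <- make_sim(seed = 2, days = 15)
  prof <- build_normal_behavior(sim$truth, n_days = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_json(prof, path)
  back <- read_profile_json(path)
  expect_equal(back$patterns[order(back$patterns$label), ],
               prof$patterns[order(prof$patterns$label), ],
               ignore_attr = TRUE)
  expect_equal(back$toilet$daily_count_range, prof$toilet$daily_count_range)
  expect_equal(back$n_days, prof$n_days)
})
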