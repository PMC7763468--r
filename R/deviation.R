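# Deviation periods and per-day point anomalies.
#
# A deviation period is a maximal run of consecutive days whose scores
# depart from the 100% baseline: similarity below a threshold, or daily
# duration outside the symmetric band [threshold, 200 - threshold]. Point
# anomalies are per-day findings: a missing expected activity, an
# abnormally long/short duration, or an abnormal occurrence frequency
# relative to the learned normal ranges (inclusive bounds).

#' Detect deviation periods in a score series
#'
#' @param scores \code{score_series} from \code{\link{score_days}}.
#' @param threshold_pct similarity threshold in (0, 100]; a day deviates
#'   when similarity < threshold or daily duration lies outside
#'   [threshold, 200 - threshold]. Default 80.
#' @param min_run minimum number of consecutive deviating days (default 2).
#' @return \code{data.frame} with \code{start_day}, \code{end_day},
#'   \code{trigger} (a short description of the score behavior), in order;
#'   zero rows when no period qualifies.
#' @export
detect_deviation_periods <- function(scores, threshold_pct = 80, min_run = 2L) {
  stopifnot(nrow(scores) > 0, threshold_pct > 0, threshold_pct <= 100)
  sim_dev <- scores$similarity_pct < threshold_pct
  dur_dev <- !is.na(scores$duration_pct) &
    (scores$duration_pct < threshold_pct |
       scores$duration_pct > 200 - threshold_pct)
  dev <- sim_dev | dur_dev
  runs <- rle(dev)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  if (!any(keep)) {
    return(data.frame(start_day = integer(), end_day = integer(),
                      trigger = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(which(keep), function(r) {
    ix <- starts[r]:ends[r]
    trig <- c(if (any(sim_dev[ix])) "similarity below threshold",
              if (any(dur_dev[ix])) "duration outside band")
    data.frame(start_day = scores$day_index[starts[r]],
               end_day = scores$day_index[ends[r]],
               trigger = paste(trig, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_anomalies <- function() {
  data.frame(day_index = integer(), label = character(), kind = character(),
             observed = numeric(), range_min = numeric(), range_max = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect point anomalies for one day
#'
#' For every pattern the routine expects: \code{missing} when the day has no
#' matching instance; \code{duration_abnormal_minus}/\code{_plus} when an
#' instance's duration falls strictly outside the pattern's duration range;
#' \code{frequency_abnormal_minus}/\code{_plus} when the day's occurrence
#' count falls strictly outside the pattern's frequency range. Toileting is
#' flagged at the day level through the frequency profile: daily visit count
#' and daily maximum visit duration against their learned ranges. All range
#' bounds are inclusive.
#'
#' @param day_instances \code{adl_instances} rows of one day.
#' @param profile \code{adl_profile}.
#' @return \code{data.frame}: \code{day_index}, \code{label}, \code{kind},
#'   \code{observed}, \code{range_min}, \code{range_max}; zero rows when the
#'   day is fully normal.
#' @export
detect_point_anomalies <- function(day_instances, profile) {
  p <- profile$patterns
  day <- if (nrow(day_instances)) day_instances$day_index[1] else NA_integer_
  matched <- match_instances_to_patterns(day_instances, profile)
  out <- empty_anomalies()
  add <- function(label, kind, observed, rng) {
    out[nrow(out) + 1L, ] <<- list(day, label, kind, observed, rng[1], rng[2])
  }
  for (k in seq_len(nrow(p))) {
    rows <- which(matched$pattern_idx == k)
    if (!length(rows)) {
      add(p$label[k], "missing", 0, c(p$dur_min[k], p$dur_max[k]))
      next
    }
    for (i in rows) {
      fl <- range_flag(matched$duration[i], c(p$dur_min[k], p$dur_max[k]))
      if (fl == "Abnormal-") add(p$label[k], "duration_abnormal_minus",
                                 matched$duration[i], c(p$dur_min[k], p$dur_max[k]))
      if (fl == "Abnormal+") add(p$label[k], "duration_abnormal_plus",
                                 matched$duration[i], c(p$dur_min[k], p$dur_max[k]))
    }
    cnt <- length(rows)
    fl <- range_flag(cnt, c(p$freq_min[k], p$freq_max[k]))
    if (fl == "Abnormal-") add(p$label[k], "frequency_abnormal_minus", cnt,
                               c(p$freq_min[k], p$freq_max[k]))
    if (fl == "Abnormal+") add(p$label[k], "frequency_abnormal_plus", cnt,
                               c(p$freq_min[k], p$freq_max[k]))
  }
  toilet <- day_instances[day_instances$label == "going_to_toilet", , drop = FALSE]
  fl <- frequency_flags(toilet, profile$toilet)
  if (fl$daily_flag == "Abnormal-")
    add("going_to_toilet", "frequency_abnormal_minus", fl$daily_count,
        profile$toilet$daily_count_range)
  if (fl$daily_flag == "Abnormal+")
    add("going_to_toilet", "frequency_abnormal_plus", fl$daily_count,
        profile$toilet$daily_count_range)
  if (fl$max_duration_flag == "Abnormal-")
    add("going_to_toilet", "duration_abnormal_minus", fl$max_duration,
        profile$toilet$max_duration_range)
  if (fl$max_duration_flag == "Abnormal+")
    add("going_to_toilet", "duration_abnormal_plus", fl$max_duration,
        profile$toilet$max_duration_range)
  out
}

#' Count abnormal duration/frequency states for a day's observation
#'
#' The observation supplies, per configured decision-support variable, a
#' crisp daily value (duration total in seconds, or occurrence count). The
#' count is the number of the 2 x |activities| states lying strictly
#' outside their normal [min, max] ranges.
#'
#' @param observation named numeric vector/list; names are variable ids such
#'   as \code{"leaving_home.duration"}, \code{"eating.frequency"}.
#' @param config \code{disease_config} (see
#'   \code{\link{read_disease_config}}); every configured variable must be
#'   present in the observation.
#' @return Integer count of abnormal states.
#' @export
count_abnormal_states <- function(observation, config) {
  ids <- vapply(config$variables, `[[`, character(1), "id")
  missing <- setdiff(ids, names(observation))
  if (length(missing)) {
    stop("observation lacks variable(s): ", paste(missing, collapse = ", "))
  }
  sum(vapply(config$variables, function(v) {
    x <- as.numeric(observation[[v$id]])
    x < v$normal_min || x > v$normal_max
  }, logical(1)))
}

#' Classify monitored days as normal/abnormal
#'
#' Point anomalies are investigated within detected deviation periods: a
#' day is classified abnormal when it lies inside a deviation period and
#' carries at least one point anomaly; days outside every period are
#' normal.
#'
#' @param instances monitored \code{adl_instances}.
#' @param profile \code{adl_profile}.
#' @param scores \code{score_series} for the same days.
#' @param threshold_pct,min_run deviation-rule parameters
#'   (see \code{\link{detect_deviation_periods}}).
#' @return List: \code{periods}, \code{anomalies} (rows for days inside
#'   periods), \code{flags} (data.frame day_index, abnormal).
#' @export
classify_days <- function(instances, profile, scores,
                          threshold_pct = 80, min_run = 2L) {
  periods <- detect_deviation_periods(scores, threshold_pct, min_run)
  days <- scores$day_index
  in_period <- rep(FALSE, length(days))
  for (r in seq_len(nrow(periods))) {
    in_period <- in_period |
      (days >= periods$start_day[r] & days <= periods$end_day[r])
  }
  anom_list <- lapply(days[in_period], function(d) {
    detect_point_anomalies(instances[instances$day_index == d, , drop = FALSE],
                           profile)
  })
  anomalies <- if (length(anom_list)) do.call(rbind, anom_list) else empty_anomalies()
  flagged_days <- unique(anomalies$day_index)
  list(periods = periods,
       anomalies = anomalies,
       flags = data.frame(day_index = days,
                          abnormal = days %in% flagged_days))
}
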