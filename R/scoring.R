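# Daily similarity and duration scores against the learned routine.
#
# For an observed activity instance (start S_d, duration D_d, end E_d) and
# the corresponding pattern (S_n, D_n, E_n = S_n + D_n):
#
#   similarity = max(0, min(E_n, E_d) - max(S_n, S_d)) * 100 / D_n
#   duration   = D_d * 100 / D_n
#
# The similarity score is the temporal intersection of the observed and
# normal intervals as a percentage of the normal duration, clamped at 0 for
# disjoint intervals; the duration score may exceed 100%.

#' Temporal-intersection similarity score (percent)
#'
#' @param start,duration observed start (s, linearized axis) and duration (s);
#'   vectors are allowed.
#' @param pattern one pattern row with \code{usual_start} and
#'   \code{usual_duration} (the pattern means).
#' @return Percentage in [0, 100].
#' @export
similarity_score <- function(start, duration, pattern) {
  if (pattern$usual_duration <= 0) stop("pattern has non-positive usual duration")
  s_n <- pattern$usual_start
  e_n <- s_n + pattern$usual_duration
  overlap <- pmin(e_n, start + duration) - pmax(s_n, start)
  pmax(0, overlap) * 100 / pattern$usual_duration
}

#' Duration score (percent of the normal duration)
#'
#' @inheritParams similarity_score
#' @return Percentage >= 0; exceeds 100 when the observed activity takes
#'   longer than the routine.
#' @export
duration_score <- function(duration, pattern) {
  if (pattern$usual_duration <= 0) stop("pattern has non-positive usual duration")
  duration * 100 / pattern$usual_duration
}

#' Assign a day's instances to profile patterns
#'
#' Eating instances go to the nearest meal pattern by start time; any other
#' label with several patterns likewise uses nearest-in-time assignment.
#'
#' @param day_instances \code{adl_instances} rows of one day (source labels).
#' @param profile \code{adl_profile}.
#' @return The instances with a \code{pattern_idx} column (row index into
#'   \code{profile$patterns}; NA for labels without a pattern, e.g.
#'   toileting).
#' @export
match_instances_to_patterns <- function(day_instances, profile) {
  p <- profile$patterns
  src <- ifelse(startsWith(p$label, "eating"), "eating", p$label)
  idx <- rep(NA_integer_, nrow(day_instances))
  for (i in seq_len(nrow(day_instances))) {
    cand <- which(src == day_instances$label[i])
    if (!length(cand)) next
    idx[i] <- cand[which.min(abs(p$usual_start[cand] - day_instances$start[i]))]
  }
  day_instances$pattern_idx <- idx
  day_instances
}

#' Daily similarity and duration scores
#'
#' The day's similarity score is the mean of per-pattern similarity scores
#' over every pattern the routine expects; a missing expected activity
#' contributes 0. When a pattern has several instances on the day, their
#' scores are averaged within the activity first. The day's duration score
#' is the mean of per-activity duration scores over the activities actually
#' present.
#'
#' @param day_instances \code{adl_instances} rows of one day.
#' @param profile \code{adl_profile} with a non-empty pattern table.
#' @return List of class \code{daily_scores}: \code{day_index},
#'   \code{similarity_pct}, \code{duration_pct},
#'   \code{per_activity_similarity}, \code{duration_pct_by_activity}
#'   (named vectors, full precision; use \code{round_half_up} for display).
#' @export
daily_scores <- function(day_instances, profile) {
  p <- profile$patterns
  if (!nrow(p)) stop("profile has no activity patterns")
  day <- if (nrow(day_instances)) day_instances$day_index[1] else NA_integer_
  matched <- match_instances_to_patterns(day_instances, profile)
  sim <- numeric(nrow(p)); names(sim) <- p$label
  dur <- rep(NA_real_, nrow(p)); names(dur) <- p$label
  for (k in seq_len(nrow(p))) {
    rows <- which(matched$pattern_idx == k)
    if (!length(rows)) next  # missing expected activity: similarity 0
    sim[k] <- mean(similarity_score(matched$start[rows],
                                    matched$duration[rows], p[k, ]))
    dur[k] <- mean(duration_score(matched$duration[rows], p[k, ]))
  }
  present <- !is.na(dur)
  structure(list(
    day_index = day,
    similarity_pct = mean(sim),
    duration_pct = if (any(present)) mean(dur[present]) else NA_real_,
    per_activity_similarity = sim,
    duration_pct_by_activity = dur[present]
  ), class = "daily_scores")
}

#' Score a sequence of observed days against the routine
#'
#' @param instances \code{adl_instances} table covering the monitoring days.
#' @param profile \code{adl_profile}.
#' @param days integer vector of day indices to score; defaults to every day
#'   in \code{instances}.
#' @return \code{data.frame} of class \code{score_series}: one row per day
#'   with \code{day_index}, \code{similarity_pct}, \code{duration_pct}, the
#'   daily toileting count and max visit duration, and their flags against
#'   the toileting profile.
#' @export
score_days <- function(instances, profile, days = NULL) {
  if (is.null(days)) days <- sort(unique(instances$day_index))
  rows <- lapply(days, function(d) {
    di <- instances[instances$day_index == d, , drop = FALSE]
    sc <- daily_scores(di, profile)
    toilet <- di[di$label == "going_to_toilet", , drop = FALSE]
    fl <- frequency_flags(toilet, profile$toilet)
    data.frame(day_index = d,
               similarity_pct = sc$similarity_pct,
               duration_pct = sc$duration_pct,
               toilet_count = fl$daily_count,
               toilet_count_flag = fl$daily_flag,
               toilet_max_duration = fl$max_duration,
               toilet_max_duration_flag = fl$max_duration_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("score_series", "data.frame")
  out
}

#' Flag a day's toileting counts against the frequency profile
#'
#' Values strictly below the profile minimum are \code{"Abnormal-"},
#' strictly above the maximum \code{"Abnormal+"}, otherwise \code{"Normal"}
#' (range boundaries are inclusive).
#'
#' @param toilet_instances the day's toileting \code{adl_instances} rows.
#' @param toilet_profile \code{toilet_profile} from the learned routine.
#' @return List: \code{daily_count}, \code{daily_flag}, \code{slot_counts},
#'   \code{slot_flags}, \code{max_duration}, \code{max_duration_flag}.
#' @export
frequency_flags <- function(toilet_instances, toilet_profile) {
  n_slots <- 24L %/% toilet_profile$slot_hours
  slot_counts <- rep(0L, n_slots)
  if (nrow(toilet_instances)) {
    slot <- floor((toilet_instances$start %% 86400) /
                    (3600 * toilet_profile$slot_hours)) + 1L
    tab <- tabulate(slot, nbins = n_slots)
    slot_counts <- as.integer(tab)
  }
  daily <- sum(slot_counts)
  max_dur <- if (nrow(toilet_instances)) max(toilet_instances$duration) else 0
  list(
    daily_count = daily,
    daily_flag = range_flag(daily, toilet_profile$daily_count_range),
    slot_counts = slot_counts,
    slot_flags = vapply(seq_len(n_slots), function(s) {
      range_flag(slot_counts[s], c(toilet_profile$slot_min[s],
                                   toilet_profile$slot_max[s]))
    }, character(1)),
    max_duration = max_dur,
    max_duration_flag = range_flag(max_dur, toilet_profile$max_duration_range)
  )
}

#' Compare a value to an inclusive normal range
#' @param x numeric value(s).
#' @param range length-2 numeric \code{c(min, max)}.
#' @return \code{"Abnormal-"}, \code{"Normal"}, or \code{"Abnormal+"}.
#' @export
range_flag <- function(x, range) {
  out <- rep("Normal", length(x))
  out[x < range[1]] <- "Abnormal-"
  out[x > range[2]] <- "Abnormal+"
  out
}

#' Write a score series to CSV (percentages rounded half-up to 2 decimals)
#' @param scores \code{score_series}.
#' @param path output path.
#' @export
write_scores_csv <- function(scores, path) {
  out <- scores
  out$similarity_pct <- round_half_up(out$similarity_pct)
  out$duration_pct <- round_half_up(out$duration_pct)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
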