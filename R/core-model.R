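# Shared domain types and time conventions.
#
# A behavioral day runs midnight -> midnight, except sleeping, which is
# anchored to the evening it begins: bedtimes after midnight up to a noon
# cutoff attach to the previous day, on an extended time axis where start
# times may exceed 86,400 s.

SECONDS_PER_DAY <- 86400L
SLEEP_ANCHOR_CUTOFF <- 43200L  # bed times before noon belong to the previous evening

#' Closed set of monitored activity labels
#'
#' The monitored routine covers four basic activities of daily living
#' (sleeping, eating, taking a shower, going to the toilet) plus one
#' instrumental activity (leaving home). Eating is split into three meal
#' sub-labels when the learned routine resolves the daily meals.
#'
#' @return Character vector of the canonical activity labels.
#' @export
activity_labels <- function() {
  c("sleeping", "eating_breakfast", "eating_lunch", "eating_dinner",
    "taking_shower", "leaving_home", "going_to_toilet")
}

#' Source-level activity labels used before meal assignment
#' @return Character vector of canonical pre-split labels.
#' @export
source_activity_labels <- function() {
  c("sleeping", "eating", "taking_shower", "leaving_home", "going_to_toilet")
}

# Fallback clock windows (seconds since midnight) used to name meal clusters
# and to assign eating instances when no learned meal pattern is available.
meal_windows <- function() {
  data.frame(
    label = c("eating_breakfast", "eating_lunch", "eating_dinner"),
    lo = c(6L, 11L, 16L) * 3600L,
    hi = c(11L, 16L, 22L) * 3600L
  )
}

#' Construct a table of activity instances
#'
#' An activity instance is one observed occurrence of an activity: a label,
#' the observation day it is anchored to, a start time in seconds on that
#' day's (possibly extended) axis, and a positive duration in seconds. The
#' end time is always \code{start + duration}.
#'
#' @param label character vector of activity labels.
#' @param day_index integer observation day (1-based).
#' @param start start time, seconds since the anchor day's midnight; values
#'   above 86,400 encode activities that began after midnight but belong to
#'   the previous behavioral day.
#' @param duration duration in seconds; must be positive.
#' @return A \code{data.frame} of class \code{adl_instances} with columns
#'   \code{label}, \code{day_index}, \code{start}, \code{duration},
#'   \code{end}, sorted by day then start.
#' @export
activity_instances <- function(label = character(), day_index = integer(),
                               start = numeric(), duration = numeric()) {
  stopifnot(length(label) == length(day_index),
            length(label) == length(start),
            length(label) == length(duration))
  if (any(duration <= 0)) stop("activity durations must be positive")
  if (any(start < 0 | start >= 2 * SECONDS_PER_DAY)) {
    stop("start times must lie in [0, 172800) seconds")
  }
  df <- data.frame(
    label = as.character(label),
    day_index = as.integer(day_index),
    start = as.numeric(start),
    duration = as.numeric(duration),
    end = as.numeric(start) + as.numeric(duration),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$day_index, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("adl_instances", "data.frame")
  df
}

#' Express an instance on an anchor day's extended time axis
#'
#' Re-anchors an activity instance observed on \code{anchor_day} or in the
#' following pre-dawn hours onto \code{anchor_day}'s extended axis, so that
#' an activity crossing midnight keeps a single linear start/end pair. The
#' duration is never changed.
#'
#' @param instance one-row \code{adl_instances} table (or a list with
#'   \code{day_index}, \code{start}, \code{duration}).
#' @param anchor_day integer day the instance should be expressed on.
#' @return The instance with \code{day_index = anchor_day} and \code{start}
#'   shifted by whole days (may exceed 86,400 s).
#' @export
linearize_instance <- function(instance, anchor_day) {
  day_offset <- instance$day_index - anchor_day
  if (any(day_offset < 0)) stop("instance precedes its anchor day")
  new_start <- instance$start + day_offset * SECONDS_PER_DAY
  if (any(new_start >= 2 * SECONDS_PER_DAY)) {
    stop("instance lies more than 24 h after the anchor day's midnight")
  }
  instance$day_index <- as.integer(rep(anchor_day, length.out = nrow_or_len(instance)))
  instance$start <- new_start
  instance$end <- new_start + instance$duration
  instance
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x$start)

#' Anchor sleep instances to the evening they begin
#'
#' Sleeping that starts after midnight (before the noon cutoff) is attributed
#' to the previous behavioral day, with its start expressed on that day's
#' extended axis. All other instances are returned unchanged.
#'
#' @param instances \code{adl_instances} table.
#' @return The table with sleep rows re-anchored; resorted by day and start.
#' @export
anchor_sleep_instances <- function(instances) {
  late <- instances$label == "sleeping" &
    instances$start < SLEEP_ANCHOR_CUTOFF & instances$day_index > 1L
  if (any(late)) {
    instances$day_index[late] <- instances$day_index[late] - 1L
    instances$start[late] <- instances$start[late] + SECONDS_PER_DAY
    instances$end[late] <- instances$start[late] + instances$duration[late]
    instances <- instances[order(instances$day_index, instances$start), , drop = FALSE]
    rownames(instances) <- NULL
  }
  instances
}

#' Assign eating instances to meal sub-labels
#'
#' Each generic \code{eating} instance is renamed to
#' \code{eating_breakfast}/\code{eating_lunch}/\code{eating_dinner} by the
#' nearest learned meal cluster start when meal patterns are supplied, and by
#' fixed clock windows (06:00-11:00 / 11:00-16:00 / 16:00-22:00, nearest
#' window edge outside them) otherwise.
#'
#' @param instances \code{adl_instances} table.
#' @param meal_starts optional named numeric vector of learned usual start
#'   times (s) for the meal labels.
#' @return The table with eating rows relabeled.
#' @export
assign_meal_labels <- function(instances, meal_starts = NULL) {
  idx <- which(instances$label == "eating")
  if (!length(idx)) return(instances)
  if (is.null(meal_starts) || !length(meal_starts)) {
    w <- meal_windows()
    centers <- (w$lo + w$hi) / 2
    names(centers) <- w$label
    meal_starts <- centers
  }
  starts <- instances$start[idx] %% SECONDS_PER_DAY
  nearest <- vapply(starts, function(s) {
    names(meal_starts)[which.min(abs(meal_starts - s))]
  }, character(1))
  instances$label[idx] <- nearest
  instances
}

#' Parse "HH:MM" or "HH:MM:SS" clock strings to seconds since midnight
#' @param x character vector of clock times.
#' @return Numeric seconds.
#' @export
clock_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2) p <- c(p, 0)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

#' Format seconds since midnight as "HH:MM:SS" (presentation only)
#' @param s numeric seconds; values past 86,400 wrap to the next day.
#' @return Character clock strings.
#' @export
seconds_to_clock <- function(s) {
  s <- round(s) %% SECONDS_PER_DAY
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Round half up (reporting convention for percentages and metrics)
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded values; exact halves round away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
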