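# Learning the normal behavior pattern: density-cluster each activity's
# (start, duration) instances, discard noise, average per cluster, and build
# the toileting frequency profile.

#' Profiling configuration
#'
#' @param eps DBSCAN radius in scaled feature units (default 2).
#' @param min_pts DBSCAN density threshold (default 4).
#' @param start_unit_s seconds per unit on the start-time axis (default 3600:
#'   start times measured in hours).
#' @param duration_unit_s seconds per unit on the duration axis (default 600:
#'   durations measured in tens of minutes).
#' @param slot_hours width of the toileting frequency slots in hours
#'   (default 2; must divide 24).
#' @return List of class \code{profiling_config}.
#' @export
profiling_config <- function(eps = 2, min_pts = 4L, start_unit_s = 3600,
                             duration_unit_s = 600, slot_hours = 2L) {
  stopifnot(eps > 0, min_pts >= 1, start_unit_s > 0, duration_unit_s > 0,
            24L %% as.integer(slot_hours) == 0L)
  structure(list(eps = eps, min_pts = as.integer(min_pts),
                 start_unit_s = start_unit_s, duration_unit_s = duration_unit_s,
                 slot_hours = as.integer(slot_hours)),
            class = "profiling_config")
}

scale_features <- function(instances, config) {
  cbind(start = instances$start / config$start_unit_s,
        duration = instances$duration / config$duration_unit_s)
}

#' Learn activity patterns for one source label
#'
#' Clusters the label's instances on (start, duration) with DBSCAN, drops
#' noise points, and summarizes each cluster into an activity pattern: usual
#' start and duration are the cluster means; the start interval and duration
#' range are the min/max over the cluster's (non-noise) instances; the
#' frequency range is the min/max daily occurrence count over the baseline
#' days, counting only non-noise instances.
#'
#' @param instances \code{adl_instances} rows sharing one source label.
#' @param config \code{\link{profiling_config}}.
#' @param n_days number of baseline days (for frequency ranges); defaults to
#'   the span of observed day indices.
#' @return \code{data.frame} with one row per pattern: \code{label},
#'   \code{usual_start}, \code{usual_duration}, \code{start_lo},
#'   \code{start_hi}, \code{dur_min}, \code{dur_max}, \code{freq_min},
#'   \code{freq_max}, \code{n_instances}; empty (with a warning) when every
#'   point is noise.
#' @export
build_activity_patterns <- function(instances, config = profiling_config(),
                                    n_days = NULL) {
  if (!nrow(instances)) return(empty_patterns())
  stopifnot(length(unique(instances$label)) == 1L)
  if (is.null(n_days)) n_days <- max(instances$day_index)
  cl <- dbscan_cluster(scale_features(instances, config),
                       eps = config$eps, min_pts = config$min_pts)
  keep <- cl$assignments != 0L
  if (!any(keep)) {
    warning("all instances marked as noise for label ", instances$label[1])
    return(empty_patterns())
  }
  rows <- lapply(sort(unique(cl$assignments[keep])), function(k) {
    sub <- instances[cl$assignments == k, , drop = FALSE]
    counts <- tabulate(sub$day_index, nbins = n_days)
    data.frame(
      label = sub$label[1],
      usual_start = mean(sub$start),
      usual_duration = mean(sub$duration),
      start_lo = min(sub$start), start_hi = max(sub$start),
      dur_min = min(sub$duration), dur_max = max(sub$duration),
      freq_min = min(counts), freq_max = max(counts),
      n_instances = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$usual_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_patterns <- function() {
  data.frame(label = character(), usual_start = numeric(),
             usual_duration = numeric(), start_lo = numeric(),
             start_hi = numeric(), dur_min = numeric(), dur_max = numeric(),
             freq_min = integer(), freq_max = integer(),
             n_instances = integer(), stringsAsFactors = FALSE)
}

# Rename eating patterns to meal sub-labels by their usual start (nearest
# fallback window center when a start lies outside every window).
name_meal_patterns <- function(patterns) {
  eat <- patterns$label == "eating"
  if (!any(eat)) return(patterns)
  w <- meal_windows()
  centers <- (w$lo + w$hi) / 2
  starts <- patterns$usual_start[eat] %% 86400
  nm <- w$label[vapply(starts, function(s) which.min(abs(centers - s)), 1L)]
  if (anyDuplicated(nm)) {
    # keep names unique: order clusters by start, assign in window order
    nm <- w$label[rank(starts, ties.method = "first")]
  }
  patterns$label[eat] <- nm
  patterns
}

#' Build the toileting frequency profile
#'
#' Toileting occurs many times a day at irregular times, so the routine is
#' summarized by frequency rather than start time: per-slot count ranges
#' (slots of \code{slot_hours} hours), the daily total count range, the
#' daily maximum single-visit duration range, and the daily total duration
#' range, all as min/max over the baseline days.
#'
#' @param instances toileting \code{adl_instances} rows.
#' @param slot_hours slot width in hours; must divide 24.
#' @param n_days number of baseline days; defaults to the observed span.
#' @return List of class \code{toilet_profile}: \code{slot_hours},
#'   \code{slot_min}/\code{slot_max} (length 24/slot_hours),
#'   \code{daily_count_range}, \code{max_duration_range},
#'   \code{total_duration_range}.
#' @export
build_toilet_profile <- function(instances, slot_hours = 2L, n_days = NULL) {
  stopifnot(24L %% as.integer(slot_hours) == 0L)
  n_slots <- 24L %/% as.integer(slot_hours)
  if (!nrow(instances)) {
    return(structure(list(slot_hours = as.integer(slot_hours),
                          slot_min = rep(0L, n_slots), slot_max = rep(0L, n_slots),
                          daily_count_range = c(0L, 0L),
                          max_duration_range = c(0, 0),
                          total_duration_range = c(0, 0)),
                     class = "toilet_profile"))
  }
  if (is.null(n_days)) n_days <- max(instances$day_index)
  slot <- floor((instances$start %% 86400) / (3600 * slot_hours)) + 1L
  counts <- matrix(0L, nrow = n_days, ncol = n_slots)
  for (i in seq_len(nrow(instances))) {
    d <- instances$day_index[i]
    counts[d, slot[i]] <- counts[d, slot[i]] + 1L
  }
  daily <- rowSums(counts)
  max_dur <- vapply(seq_len(n_days), function(d) {
    dur <- instances$duration[instances$day_index == d]
    if (length(dur)) max(dur) else 0
  }, numeric(1))
  tot_dur <- vapply(seq_len(n_days), function(d) {
    sum(instances$duration[instances$day_index == d])
  }, numeric(1))
  structure(list(
    slot_hours = as.integer(slot_hours),
    slot_min = apply(counts, 2, min), slot_max = apply(counts, 2, max),
    daily_count_range = c(min(daily), max(daily)),
    max_duration_range = c(min(max_dur), max(max_dur)),
    total_duration_range = c(min(tot_dur), max(tot_dur))
  ), class = "toilet_profile")
}

#' Learn the full normal behavior pattern from a baseline window
#'
#' Routine activities (sleeping, eating, taking a shower, leaving home) are
#' clustered per label and summarized into activity patterns; eating
#' clusters are named as the daily meals; toileting is summarized by its
#' frequency profile. Labels with no instances are omitted with a warning
#' (a housebound person simply has no leaving-home pattern). Daily
#' duration/frequency aggregates per source label (min/max over baseline
#' days, noise instances excluded) are kept for configuring the
#' decision-support normal ranges.
#'
#' @param instances \code{adl_instances} table for the baseline window.
#' @param config \code{\link{profiling_config}}.
#' @param n_days baseline length in days; defaults to the observed span.
#' @return List of class \code{adl_profile}: \code{patterns} (pattern
#'   data.frame), \code{toilet} (\code{toilet_profile}),
#'   \code{daily_ranges} (per-label daily duration-total and count ranges),
#'   \code{config}, \code{n_days}.
#' @export
build_normal_behavior <- function(instances, config = profiling_config(),
                                  n_days = NULL) {
  if (!nrow(instances)) stop("no instances in the baseline window")
  if (is.null(n_days)) n_days <- max(instances$day_index)
  routine_labels <- setdiff(source_activity_labels(), "going_to_toilet")
  pat_list <- list()
  noise_mask <- rep(FALSE, nrow(instances))
  for (lab in routine_labels) {
    rows <- which(instances$label == lab)
    if (!length(rows)) {
      warning("no baseline instances for label ", lab, "; label omitted")
      next
    }
    sub <- instances[rows, , drop = FALSE]
    cl <- dbscan_cluster(scale_features(sub, config),
                         eps = config$eps, min_pts = config$min_pts)
    noise_mask[rows[cl$assignments == 0L]] <- TRUE
    pats <- build_activity_patterns(sub, config, n_days = n_days)
    if (nrow(pats)) pat_list[[lab]] <- pats
  }
  patterns <- if (length(pat_list)) do.call(rbind, pat_list) else empty_patterns()
  rownames(patterns) <- NULL
  patterns <- name_meal_patterns(patterns)
  toilet_rows <- instances$label == "going_to_toilet"
  toilet <- build_toilet_profile(instances[toilet_rows, , drop = FALSE],
                                 slot_hours = config$slot_hours, n_days = n_days)
  clean <- instances[!noise_mask, , drop = FALSE]
  structure(list(patterns = patterns, toilet = toilet,
                 daily_ranges = daily_label_ranges(clean, n_days),
                 config = config, n_days = n_days),
            class = "adl_profile")
}

# Per source label: min/max over baseline days of the daily duration total
# and the daily occurrence count. Days where a label is absent contribute
# zeros only for labels absent that day by routine variation, so ranges
# reflect the observed days as-is.
daily_label_ranges <- function(instances, n_days) {
  labs <- intersect(source_activity_labels(), unique(instances$label))
  rows <- lapply(labs, function(lab) {
    sub <- instances[instances$label == lab, , drop = FALSE]
    dur <- vapply(seq_len(n_days), function(d) {
      sum(sub$duration[sub$day_index == d])
    }, numeric(1))
    cnt <- vapply(seq_len(n_days), function(d) {
      sum(sub$day_index == d)
    }, numeric(1))
    data.frame(label = lab, dur_min = min(dur), dur_max = max(dur),
               freq_min = min(cnt), freq_max = max(cnt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.adl_profile <- function(x, ...) {
  cat(sprintf("Normal behavior pattern (%d baseline day(s))\n", x$n_days))
  if (nrow(x$patterns)) {
    p <- x$patterns
    cat(sprintf("  %-17s start %s  duration %5.0f s  [n=%d]\n",
                p$label, seconds_to_clock(p$usual_start), p$usual_duration,
                p$n_instances), sep = "")
  }
  cat(sprintf("  going_to_toilet   %d-%d visits/day (%dh slots)\n",
              x$toilet$daily_count_range[1], x$toilet$daily_count_range[2],
              x$toilet$slot_hours))
  invisible(x)
}

#' Serialize / deserialize a profile as JSON
#'
#' The JSON document maps each activity to its pattern list
#' (\code{usual_start_s}, \code{usual_duration_s}, \code{start_interval},
#' \code{duration_range}, \code{frequency_range}) plus a toileting profile
#' block, with stable key order for diffable output.
#'
#' @param profile \code{adl_profile}.
#' @param path file path.
#' @return \code{read_profile_json} returns the \code{adl_profile}.
#' @export
write_profile_json <- function(profile, path) {
  p <- profile$patterns
  by_label <- lapply(split(p, p$label), function(sub) {
    lapply(seq_len(nrow(sub)), function(i) list(
      usual_start_s = sub$usual_start[i],
      usual_duration_s = sub$usual_duration[i],
      start_interval = c(sub$start_lo[i], sub$start_hi[i]),
      duration_range = c(sub$dur_min[i], sub$dur_max[i]),
      frequency_range = c(sub$freq_min[i], sub$freq_max[i]),
      n_instances = sub$n_instances[i]))
  })
  doc <- list(
    activities = by_label[order(names(by_label))],
    toilet = unclass(profile$toilet),
    daily_ranges = profile$daily_ranges,
    config = unclass(profile$config),
    n_days = profile$n_days
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  rows <- list()
  for (lab in names(doc$activities)) {
    for (p in doc$activities[[lab]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = lab, usual_start = p$usual_start_s,
        usual_duration = p$usual_duration_s,
        start_lo = p$start_interval[1], start_hi = p$start_interval[2],
        dur_min = p$duration_range[1], dur_max = p$duration_range[2],
        freq_min = as.integer(p$frequency_range[1]),
        freq_max = as.integer(p$frequency_range[2]),
        n_instances = as.integer(p$n_instances), stringsAsFactors = FALSE)
    }
  }
  patterns <- if (length(rows)) do.call(rbind, rows) else empty_patterns()
  patterns <- patterns[order(patterns$usual_start), , drop = FALSE]
  rownames(patterns) <- NULL
  toilet <- doc$toilet
  toilet$slot_hours <- as.integer(toilet$slot_hours)
  class(toilet) <- "toilet_profile"
  cfg <- doc$config
  config <- profiling_config(cfg$eps, cfg$min_pts, cfg$start_unit_s,
                             cfg$duration_unit_s, cfg$slot_hours)
  structure(list(patterns = patterns, toilet = toilet,
                 daily_ranges = as.data.frame(doc$daily_ranges),
                 config = config, n_days = doc$n_days),
            class = "adl_profile")
}
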