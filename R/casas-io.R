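# Reading and writing activity-labeled smart-home sensor logs.
#
# The log dialect is whitespace-delimited: date, time, sensor id, sensor
# message, activity label, and an optional begin/end token, one sensor
# reading per line, e.g.
#
#   2012-08-01 09:44:00.00 M009 ON Eat begin
#
# Sensor id prefixes: "M" infrared motion, "MA" wide-area infrared motion,
# "D" magnetic door.

#' Parse an activity-labeled sensor event log
#'
#' @param lines character vector of log lines (or a length-1 path read with
#'   \code{readLines} by the caller); empty/whitespace-only lines ignored.
#' @return \code{data.frame} with columns \code{timestamp} (POSIXct, UTC),
#'   \code{date}, \code{time}, \code{sensor_id}, \code{sensor_class},
#'   \code{message}, \code{activity_label}, \code{marker}
#'   (\code{"begin"}/\code{"end"}/\code{"none"}), in file order. Malformed
#'   lines are skipped with a warning carrying their count.
#' @export
parse_casas_events <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    date = character(), time = character(), sensor_id = character(),
    sensor_class = character(), message = character(),
    activity_label = character(), marker = character(),
    stringsAsFactors = FALSE
  )
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n_fields <- lengths(fields)
  ok <- n_fields >= 5 & n_fields <= 6
  ts <- rep(as.POSIXct(NA, tz = "UTC"), length(lines))
  if (any(ok)) {
    dt <- vapply(fields[ok], function(f) paste(f[1], f[2]), character(1))
    parsed <- as.POSIXct(dt, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
    retry <- is.na(parsed)
    if (any(retry)) {
      parsed[retry] <- as.POSIXct(dt[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
    }
    ts[ok] <- parsed
  }
  ok <- ok & !is.na(ts)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed log line(s)", n_bad))
  }
  if (!any(ok)) return(empty)
  fields <- fields[ok]
  sensor <- vapply(fields, `[`, character(1), 3)
  marker <- vapply(fields, function(f) {
    if (length(f) >= 6 && f[6] %in% c("begin", "end")) f[6] else "none"
  }, character(1))
  out <- data.frame(
    timestamp = ts[ok],
    date = vapply(fields, `[`, character(1), 1),
    time = vapply(fields, `[`, character(1), 2),
    sensor_id = sensor,
    sensor_class = sensor_class(sensor),
    message = vapply(fields, `[`, character(1), 4),
    activity_label = vapply(fields, `[`, character(1), 5),
    marker = marker,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify a sensor id by its prefix
#' @param sensor_id character vector of sensor ids.
#' @return \code{"wide_area_motion"} for MA, \code{"motion"} for M,
#'   \code{"door"} for D, otherwise \code{"other"}.
#' @export
sensor_class <- function(sensor_id) {
  out <- rep("other", length(sensor_id))
  out[startsWith(sensor_id, "D")] <- "door"
  out[startsWith(sensor_id, "M")] <- "motion"
  out[startsWith(sensor_id, "MA")] <- "wide_area_motion"
  out
}

#' Default source-label canonicalization map
#'
#' Maps raw log activity labels to the canonical monitored labels. Labels
#' with role \code{"pair"} are bounded by begin/end markers on the same
#' label; \code{leaving_home} is bounded by a departure label
#' (role \code{"begin"}) and a return label (role \code{"end"}), its
#' duration being the time away from home. Unlisted labels (Relax, Cook,
#' Other activity, ...) are ignored.
#'
#' @return \code{data.frame} with columns \code{source}, \code{target},
#'   \code{role}.
#' @export
default_label_map <- function() {
  data.frame(
    source = c("Sleep", "Eat", "Bathe", "Toilet", "Bed_Toilet_Transition",
               "Leave_Home", "Enter_Home"),
    target = c("sleeping", "eating", "taking_shower", "going_to_toilet",
               "going_to_toilet", "leaving_home", "leaving_home"),
    role = c("pair", "pair", "pair", "pair", "pair", "begin", "end"),
    stringsAsFactors = FALSE
  )
}

#' Read / write a label map as JSON
#' @param path file path.
#' @return \code{read_label_map} returns the label-map data.frame.
#' @export
read_label_map <- function(path) {
  m <- jsonlite::fromJSON(path)
  stopifnot(all(c("source", "target", "role") %in% names(m)))
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' @rdname read_label_map
#' @param map label-map data.frame.
#' @export
write_label_map <- function(map, path) {
  jsonlite::write_json(map, path, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Pair begin/end sensor events into activity instances
#'
#' For each canonical label, matching begins and ends are paired
#' first-begin/first-end (activities of different labels may interleave or
#' nest). The instance duration is end time minus begin time; for leaving
#' home it is the return time minus the departure time. A begin without a
#' matching end before the next begin of the same label (or vice versa) is
#' dropped with a warning; an end preceding any begin is an error when it is
#' the only event of its label.
#'
#' Day indexing: day 1 is the date of the earliest event; sleeping that
#' starts after midnight before noon is anchored to the previous day's
#' extended axis.
#'
#' @param events event table from \code{\link{parse_casas_events}},
#'   time-sorted.
#' @param label_map label map (see \code{\link{default_label_map}}).
#' @return \code{adl_instances} table sorted by day and start.
#' @export
pair_activity_instances <- function(events, label_map = default_label_map()) {
  if (!nrow(events)) return(activity_instances())
  keep <- events$activity_label %in% label_map$source
  events <- events[keep, , drop = FALSE]
  if (!nrow(events)) return(activity_instances())
  if (is.unsorted(events$timestamp)) stop("events must be time-sorted")

  day0 <- as.Date(min(events$timestamp))
  ev_day <- as.integer(as.Date(events$timestamp) - day0) + 1L
  ev_sec <- as.numeric(events$timestamp) - as.numeric(as.POSIXct(
    paste(as.Date(events$timestamp), "00:00:00"), tz = "UTC"))
  map_idx <- match(events$activity_label, label_map$source)
  target <- label_map$target[map_idx]
  role <- label_map$role[map_idx]
  # normalize: pair-role events use their begin/end marker; begin/end-role
  # labels (departure/return) are markers in themselves
  eff_marker <- ifelse(role == "pair", events$marker, role)

  out_label <- character(); out_day <- integer()
  out_start <- numeric(); out_dur <- numeric()
  n_dropped <- 0L
  for (lab in unique(target)) {
    sel <- which(target == lab)
    mk <- eff_marker[sel]
    open <- NA_integer_  # index into sel of the pending begin
    for (j in seq_along(sel)) {
      if (mk[j] == "begin") {
        if (!is.na(open)) n_dropped <- n_dropped + 1L  # begin without end
        open <- j
      } else if (mk[j] == "end") {
        if (is.na(open)) {
          if (j == 1L && length(sel) == 1L) stop("end marker precedes any begin for label ", lab)
          n_dropped <- n_dropped + 1L
          next
        }
        i_beg <- sel[open]; i_end <- sel[j]
        dur <- as.numeric(events$timestamp[i_end]) - as.numeric(events$timestamp[i_beg])
        if (dur < 0) stop("end before begin for label ", lab)
        if (dur > 0) {
          out_label <- c(out_label, lab)
          out_day <- c(out_day, ev_day[i_beg])
          out_start <- c(out_start, ev_sec[i_beg])
          out_dur <- c(out_dur, dur)
        }
        open <- NA_integer_
      }
    }
    if (!is.na(open)) n_dropped <- n_dropped + 1L
  }
  if (n_dropped > 0) {
    warning(sprintf("dropped %d unpaired begin/end marker(s)", n_dropped))
  }
  inst <- activity_instances(out_label, out_day, out_start, out_dur)
  anchor_sleep_instances(inst)
}

#' Write activity instances to CSV
#' @param instances \code{adl_instances} table.
#' @param path output path.
#' @export
write_instances_csv <- function(instances, path) {
  utils::write.csv(
    data.frame(day_index = instances$day_index, label = instances$label,
               start_s = instances$start, duration_s = instances$duration),
    path, row.names = FALSE)
  invisible(path)
}

#' Write sensor events back to the log dialect
#' @param events event table (as from \code{\link{parse_casas_events}}).
#' @param path output path; omit to return the lines.
#' @return Character vector of log lines, invisibly when written to a file.
#' @export
write_casas_log <- function(events, path = NULL) {
  marker <- ifelse(events$marker == "none", "", paste0(" ", events$marker))
  lines <- sprintf("%s %s %s %s %s%s", events$date, events$time,
                   events$sensor_id, events$message, events$activity_label,
                   marker)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
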