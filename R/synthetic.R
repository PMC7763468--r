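# Seeded synthetic activity-log generator with injectable anomaly
# scenarios, so every stage of the pipeline is testable without any real
# recording. Start times and durations are truncated-Gaussian draws around
# a fixed routine; toileting counts are Poisson per time slot. Events are
# emitted in the same whitespace-delimited dialect the parser reads.

#' Default routine specification
#'
#' One activity row per routine occurrence: clock start mean/SD (s),
#' duration mean/SD (s). The defaults portray a highly regular elderly
#' routine consistent with the normal ranges used by the shipped
#' decision-support configuration (sleep around 36,000 s within
#' 31,200-40,800; about 11 toilet visits/day; leaving home roughly
#' 9000-14,400 s).
#'
#' @param days number of days to generate (default 63).
#' @param seed integer seed; every draw is governed by it.
#' @return List of class \code{routine_spec}: \code{activities} data.frame
#'   (label, start_mean, start_sd, duration_mean, duration_sd),
#'   \code{toilet} (slot_hours, slot_means, visit_duration_mean/sd),
#'   \code{days}, \code{seed}.
#' @export
routine_spec <- function(days = 63L, seed = 1L) {
  activities <- data.frame(
    label = c("sleeping", "eating", "eating", "eating", "taking_shower",
              "leaving_home"),
    start_mean = c(81000, 35040, 45000, 68400, 63000, 50400),
    start_sd = c(900, 180, 180, 180, 120, 600),
    duration_mean = c(36000, 1200, 1500, 1400, 900, 11700),
    duration_sd = c(900, 150, 150, 150, 90, 900),
    stringsAsFactors = FALSE
  )
  toilet <- list(
    slot_hours = 2L,
    slot_means = c(0.2, 0.1, 0.1, 0.6, 1.3, 1.2, 1.1, 1.1, 1.0, 1.2, 1.4, 1.7),
    visit_duration_mean = 240, visit_duration_sd = 60
  )
  structure(list(activities = activities, toilet = toilet,
                 days = as.integer(days), seed = as.integer(seed)),
            class = "routine_spec")
}

trunc_norm <- function(n, mean, sd, lower = 1) {
  pmax(lower, stats::rnorm(n, mean, sd))
}

# Push overlapping same-label visits apart so begin/end pairs never nest
# within one label (keeps event pairing exact).
space_out <- function(starts, durations, gap = 60) {
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      lo <- starts[i - 1] + durations[i - 1] + gap
      if (starts[i] < lo) starts[i] <- lo
    }
  }
  starts
}

#' Generate a routine log with ground truth
#'
#' For each day and routine activity, draws start and duration from the
#' stated Gaussians (truncated at zero) and emits a begin/end event pair;
#' toileting visit counts are drawn per slot from a Poisson with the stated
#' mean, visit times uniform within the slot. Deterministic for a fixed
#' seed. Errors when the routine's mean intervals overlap (infeasible
#' routine).
#'
#' @param spec \code{\link{routine_spec}}.
#' @return List of class \code{adl_simulation}: \code{events} (event
#'   table), \code{truth} (ground-truth \code{adl_instances}), \code{spec}.
#' @export
generate_routine_log <- function(spec) {
  acts <- spec$activities
  non_sleep <- acts[acts$label != "sleeping", ]
  ord <- order(non_sleep$start_mean)
  ends <- non_sleep$start_mean[ord] + non_sleep$duration_mean[ord]
  if (any(ends[-length(ends)] > non_sleep$start_mean[ord][-1])) {
    stop("infeasible routine: mean activity intervals overlap")
  }
  set.seed(spec$seed)
  label <- character(); day <- integer(); start <- numeric(); dur <- numeric()
  n_slots <- 24L %/% spec$toilet$slot_hours
  slot_w <- 3600 * spec$toilet$slot_hours
  for (d in seq_len(spec$days)) {
    s <- round(trunc_norm(nrow(acts), acts$start_mean, acts$start_sd, lower = 0))
    dd <- round(trunc_norm(nrow(acts), acts$duration_mean, acts$duration_sd))
    label <- c(label, acts$label)
    day <- c(day, rep(d, nrow(acts)))
    start <- c(start, s)
    dur <- c(dur, dd)
    counts <- stats::rpois(n_slots, spec$toilet$slot_means)
    t_all <- numeric(0); v_all <- numeric(0)
    for (sl in which(counts > 0)) {
      t0 <- sort(round(stats::runif(counts[sl], (sl - 1) * slot_w,
                                    sl * slot_w - 600)))
      v <- round(trunc_norm(counts[sl], spec$toilet$visit_duration_mean,
                            spec$toilet$visit_duration_sd, lower = 30))
      t_all <- c(t_all, t0); v_all <- c(v_all, v)
    }
    if (length(t_all)) {
      t_all <- space_out(t_all, v_all)
      label <- c(label, rep("going_to_toilet", length(t_all)))
      day <- c(day, rep(d, length(t_all)))
      start <- c(start, t_all)
      dur <- c(dur, v_all)
    }
  }
  truth <- activity_instances(label, day, start, dur)
  list_out <- list(events = instances_to_events(truth), truth = truth,
                   spec = spec)
  structure(list_out, class = "adl_simulation")
}

# Emit begin/end sensor events for ground-truth instances, in the log
# dialect. Sleep past midnight rolls its end to the next date naturally via
# POSIXct arithmetic.
instances_to_events <- function(truth, base_date = as.Date("2012-08-01")) {
  sensor_for <- c(sleeping = "M021", eating = "M009", taking_shower = "M013",
                  leaving_home = "D002", going_to_toilet = "MA016")
  src_for <- c(sleeping = "Sleep", eating = "Eat", taking_shower = "Bathe",
               leaving_home = "Leave_Home", going_to_toilet = "Toilet")
  base <- as.POSIXct(paste(base_date, "00:00:00"), tz = "UTC")
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    lab <- truth$label[i]
    t_beg <- base + (truth$day_index[i] - 1) * 86400 + truth$start[i]
    t_end <- t_beg + truth$duration[i]
    if (lab == "leaving_home") {
      data.frame(timestamp = c(t_beg, t_end), sensor_id = "D002",
                 message = c("OPEN", "OPEN"),
                 activity_label = c("Leave_Home", "Enter_Home"),
                 marker = "none", stringsAsFactors = FALSE)
    } else {
      data.frame(timestamp = c(t_beg, t_end),
                 sensor_id = sensor_for[[lab]],
                 message = c("ON", "OFF"),
                 activity_label = src_for[[lab]],
                 marker = c("begin", "end"), stringsAsFactors = FALSE)
    }
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ev$date <- format(ev$timestamp, "%Y-%m-%d", tz = "UTC")
  ev$time <- format(ev$timestamp, "%H:%M:%OS2", tz = "UTC")
  ev$sensor_class <- sensor_class(ev$sensor_id)
  rownames(ev) <- NULL
  ev[, c("timestamp", "date", "time", "sensor_id", "sensor_class",
         "message", "activity_label", "marker")]
}

#' Anomaly scenario constructor
#'
#' @param edits list of edits; each edit is a list with \code{days}
#'   (integer vector), \code{activity} (source label; ignored for
#'   \code{set_toilet_count}), \code{action} one of \code{"drop"},
#'   \code{"scale_duration"}, \code{"shift_start"},
#'   \code{"set_toilet_count"}, and \code{factor} / \code{amount} /
#'   \code{count} as the action requires (\code{set_toilet_count} also
#'   accepts \code{duration_factor} for the visit length).
#' @param abnormal_days integer vector of ground-truth abnormal days; every
#'   other day in the log is labeled normal.
#' @return List of class \code{anomaly_scenario}.
#' @export
anomaly_scenario <- function(edits, abnormal_days) {
  structure(list(edits = edits, abnormal_days = as.integer(abnormal_days)),
            class = "anomaly_scenario")
}

#' Inject an anomaly scenario into a simulated log
#'
#' Applies the scenario's edits to the ground-truth instances, re-emits the
#' event log, and returns per-day normal/abnormal labels. Editing an
#' activity absent from the log is an error; an empty scenario returns the
#' log unchanged with all days normal.
#'
#' @param sim \code{adl_simulation} from \code{\link{generate_routine_log}}.
#' @param scenario \code{\link{anomaly_scenario}}.
#' @param seed seed for redrawn toileting visits.
#' @return \code{adl_simulation} with an extra \code{labels} data.frame
#'   (\code{day_index}, \code{abnormal}).
#' @export
inject_anomaly_scenario <- function(sim, scenario, seed = sim$spec$seed + 1L) {
  truth <- sim$truth
  if (length(scenario$edits) &&
      any(unlist(lapply(scenario$edits, `[[`, "days")) > sim$spec$days)) {
    stop("scenario edits reference days outside the log span")
  }
  set.seed(seed)
  for (e in scenario$edits) {
    if (identical(e$action, "set_toilet_count")) {
      for (d in e$days) {
        truth <- truth[!(truth$day_index == d &
                           truth$label == "going_to_toilet"), , drop = FALSE]
        k <- e$count
        t0 <- sort(round(stats::runif(k, 6 * 3600, 23 * 3600)))
        fac <- if (is.null(e$duration_factor)) 1 else e$duration_factor
        v <- round(trunc_norm(k, sim$spec$toilet$visit_duration_mean * fac,
                              sim$spec$toilet$visit_duration_sd * fac,
                              lower = 30))
        t0 <- space_out(t0, v)
        truth <- rbind(truth, activity_instances(
          rep("going_to_toilet", k), rep(d, k), t0, v))
      }
      next
    }
    sel <- truth$day_index %in% e$days & truth$label == e$activity
    if (!is.null(e$start_window)) {
      sel <- sel & truth$start >= e$start_window[1] &
        truth$start <= e$start_window[2]
    }
    if (!any(sel)) stop("edit targets absent activity: ", e$activity)
    if (identical(e$action, "drop")) {
      truth <- truth[!sel, , drop = FALSE]
    } else if (identical(e$action, "scale_duration")) {
      truth$duration[sel] <- pmax(1, round(truth$duration[sel] * e$factor))
      truth$end[sel] <- truth$start[sel] + truth$duration[sel]
    } else if (identical(e$action, "shift_start")) {
      truth$start[sel] <- truth$start[sel] + e$amount
      truth$end[sel] <- truth$start[sel] + truth$duration[sel]
    } else {
      stop("unknown edit action: ", e$action)
    }
  }
  truth <- truth[order(truth$day_index, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  class(truth) <- c("adl_instances", "data.frame")
  labels <- data.frame(day_index = seq_len(sim$spec$days),
                       abnormal = seq_len(sim$spec$days) %in%
                         scenario$abnormal_days)
  structure(list(events = instances_to_events(truth), truth = truth,
                 spec = sim$spec, labels = labels),
            class = "adl_simulation")
}

#' A gastrointestinal-style deviation episode
#'
#' A 13-day episode with onset, escalation, peak and recovery: shortened
#' and delayed lunches at onset and recovery, skipped lunches with reduced
#' dinners while escalating, and at the peak skipped lunches, halved
#' breakfast/dinner, housebound days (no leaving home), short late sleep,
#' and strongly elevated toileting (24 visits/day with longer visits).
#'
#' @param start_day first episode day (default 44).
#' @return \code{\link{anomaly_scenario}} labeling the 13 episode days
#'   abnormal.
#' @export
gastro_episode_scenario <- function(start_day = 44L) {
  d <- function(k) start_day + k - 1L  # episode day k (1..13)
  lunch_window <- c(11 * 3600, 16 * 3600)
  dinner_window <- c(16 * 3600, 22 * 3600)
  breakfast_window <- c(5 * 3600, 11 * 3600)
  onset <- function(days) list(
    list(days = days, activity = "eating", action = "scale_duration",
         factor = 0.4, start_window = lunch_window),
    list(days = days, activity = "eating", action = "shift_start",
         amount = 3600, start_window = lunch_window),
    list(days = days, activity = "eating", action = "scale_duration",
         factor = 0.7, start_window = dinner_window))
  escalate <- function(days) list(
    list(days = days, activity = "eating", action = "drop",
         start_window = lunch_window),
    list(days = days, activity = "eating", action = "scale_duration",
         factor = 0.7, start_window = dinner_window))
  peak_days <- d(5):d(9)
  peak <- list(
    list(days = peak_days, activity = "eating", action = "drop",
         start_window = lunch_window),
    list(days = peak_days, activity = "eating", action = "scale_duration",
         factor = 0.5, start_window = breakfast_window),
    list(days = peak_days, activity = "eating", action = "scale_duration",
         factor = 0.5, start_window = dinner_window),
    list(days = peak_days, activity = "leaving_home", action = "drop"),
    list(days = peak_days, activity = "sleeping", action = "scale_duration",
         factor = 0.7),
    list(days = peak_days, activity = "sleeping", action = "shift_start",
         amount = 2 * 3600),
    list(days = peak_days, action = "set_toilet_count", count = 24L,
         duration_factor = 1.6))
  anomaly_scenario(
    edits = c(onset(c(d(1), d(2))), escalate(c(d(3), d(4))), peak,
              escalate(c(d(10), d(11))), onset(c(d(12), d(13)))),
    abnormal_days = d(1):d(13))
}
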