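# End-to-end monitoring pipeline: learn the routine on a baseline window,
# score the monitored days, detect deviation periods and point anomalies,
# assess the suspected-disease level per deviation day, and (when ground
# truth exists) evaluate day-level detection.

#' Run the full monitoring pipeline on an event log
#'
#' @param events parsed event table, or a path to a log file.
#' @param baseline_days number of leading days used to learn the routine
#'   (default 30).
#' @param label_map label canonicalization map.
#' @param config \code{\link{profiling_config}}.
#' @param threshold_pct,min_run deviation-rule parameters.
#' @param disease_config optional \code{disease_config}; by default one is
#'   derived from the learned profile's daily normal ranges
#'   (\code{\link{disease_config_from_profile}}).
#' @param truth_labels optional data.frame (\code{day_index},
#'   \code{abnormal}) for evaluation of the monitored days.
#' @param out_dir optional directory; when given, writes
#'   \code{profile.json}, \code{scores.csv}, \code{anomalies.csv},
#'   \code{assessments.csv}, \code{metrics.json} and a run manifest.
#' @return List of class \code{adl_pipeline_result}: \code{profile},
#'   \code{scores}, \code{periods}, \code{anomalies}, \code{flags},
#'   \code{assessments} (data.frame), \code{confusion} (or NULL),
#'   \code{disease_config}.
#' @export
run_pipeline <- function(events, baseline_days = 30L,
                         label_map = default_label_map(),
                         config = profiling_config(),
                         threshold_pct = 80, min_run = 2L,
                         disease_config = NULL, truth_labels = NULL,
                         out_dir = NULL) {
  if (is.character(events)) {
    events <- parse_casas_events(readLines(events))
  }
  instances <- pair_activity_instances(events, label_map)
  instances <- assign_day_labels(instances)
  baseline <- instances[instances$day_index <= baseline_days, , drop = FALSE]
  monitored <- instances[instances$day_index > baseline_days, , drop = FALSE]
  if (!nrow(baseline)) stop("pipeline/profile: baseline window is empty")
  if (!nrow(monitored)) stop("pipeline/score: no monitored days after baseline")
  profile <- build_normal_behavior(baseline, config, n_days = baseline_days)
  scores <- score_days(monitored, profile)
  cls <- classify_days(monitored, profile, scores, threshold_pct, min_run)
  if (is.null(disease_config)) {
    disease_config <- disease_config_from_profile(profile)
  }
  assess_days <- sort(unique(cls$anomalies$day_index))
  assessments <- do.call(rbind, lapply(assess_days, function(d) {
    obs <- daily_observation(
      monitored[monitored$day_index == d, , drop = FALSE], disease_config)
    a <- assess_disease_day(obs, disease_config, day_index = d)
    data.frame(day_index = d, level = a$level, category = a$category,
               alert = a$alert, n_abnormal_states = a$n_abnormal_states,
               stringsAsFactors = FALSE)
  }))
  if (is.null(assessments)) {
    assessments <- data.frame(day_index = integer(), level = numeric(),
                              category = character(), alert = character(),
                              n_abnormal_states = integer(),
                              stringsAsFactors = FALSE)
  }
  confusion <- NULL
  if (!is.null(truth_labels)) {
    truth <- truth_labels[match(cls$flags$day_index, truth_labels$day_index),
                          "abnormal"]
    confusion <- confusion_counts(cls$flags$abnormal, truth)
  }
  result <- structure(list(profile = profile, scores = scores,
                           periods = cls$periods, anomalies = cls$anomalies,
                           flags = cls$flags, assessments = assessments,
                           confusion = confusion,
                           disease_config = disease_config),
                      class = "adl_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir,
                                                  baseline_days, threshold_pct,
                                                  min_run, config)
  result
}

# Day indices are assigned by the pairing step already; this hook exists so
# callers can re-anchor instances loaded from other sources.
assign_day_labels <- function(instances) instances

write_pipeline_artifacts <- function(result, out_dir, baseline_days,
                                     threshold_pct, min_run, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_json(result$profile, file.path(out_dir, "profile.json"))
  write_scores_csv(result$scores, file.path(out_dir, "scores.csv"))
  utils::write.csv(result$anomalies, file.path(out_dir, "anomalies.csv"),
                   row.names = FALSE)
  utils::write.csv(result$assessments, file.path(out_dir, "assessments.csv"),
                   row.names = FALSE)
  metrics <- if (!is.null(result$confusion)) {
    c(unclass(result$confusion),
      list(sensitivity = sensitivity(result$confusion),
           accuracy = accuracy(result$confusion)))
  } else list()
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("adlmonitor")),
    baseline_days = baseline_days, threshold_pct = threshold_pct,
    min_run = min_run, profiling = unclass(config),
    n_periods = nrow(result$periods), n_anomalies = nrow(result$anomalies),
    n_assessed_days = nrow(result$assessments),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.adl_pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d monitored day(s), %d deviation period(s), %d anomaly record(s)\n",
              nrow(x$scores), nrow(x$periods), nrow(x$anomalies)))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}
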