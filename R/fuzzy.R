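# Mamdani fuzzy decision-support system for suspected-disease assessment.
#
# Inputs are linguistic variables: for each disease-relevant activity, a
# daily duration (s) and a daily frequency (count), each carrying three
# trapezoidal fuzzy subsets Abnormal- / Normal / Abnormal+ built around the
# person's normal ranges. Rules are AND/OR clauses over these subsets with
# consequents on the output level sets Low / High / Very high defined on
# [0, 1]. Inference is min/max (clipped consequents aggregated pointwise by
# max); defuzzification is the discrete center of gravity
#   y* = sum(y_i mu(y_i)) / sum(mu(y_i))
# on a uniform grid over [0, 1].

#' Trapezoidal fuzzy set
#'
#' Membership is 0 outside (a, d), 1 on [b, c], and linear on (a, b) and
#' (c, d). Infinite corners give open shoulders; equal corners give crisp
#' edges.
#'
#' @param name subset name.
#' @param a,b,c,d corners with a <= b <= c <= d (\code{-Inf}/\code{Inf}
#'   allowed).
#' @return List of class \code{fuzzy_set}.
#' @export
fuzzy_trapezoid <- function(name, a, b, c, d) {
  stopifnot(a <= b, b <= c, c <= d)
  structure(list(name = name, a = a, b = b, c = c, d = d),
            class = "fuzzy_set")
}

#' Trapezoidal membership degree
#'
#' @param x numeric value(s).
#' @param set \code{fuzzy_set}.
#' @return Degree(s) in [0, 1]; a total function (degenerate corners give a
#'   crisp spike: membership 1 exactly on [b, c]).
#' @export
trapezoid_membership <- function(x, set) {
  out <- numeric(length(x))
  on_plateau <- x >= set$b & x <= set$c
  out[on_plateau] <- 1
  rising <- x > set$a & x < set$b
  if (any(rising)) out[rising] <- (x[rising] - set$a) / (set$b - set$a)
  falling <- x > set$c & x < set$d
  if (any(falling)) out[falling] <- (set$d - x[falling]) / (set$d - set$c)
  out
}

#' Build the three subsets of a decision-support variable
#'
#' Default corner geometry for a variable with normal range [m, M]: a
#' transition half-width \code{w = max(alpha * (M - m), w_min)} places
#' Abnormal- = (-Inf, -Inf, m - w, m), Normal = (m - w, m, M, M + w),
#' Abnormal+ = (M, M + w, Inf, Inf), so the Normal plateau is exactly the
#' inclusive normal range. Per-variable corner overrides replace this
#' default (used by shipped configurations calibrated to expert knowledge).
#'
#' @param id variable id, \code{"<label>.duration"} or
#'   \code{"<label>.frequency"}.
#' @param label activity label.
#' @param aspect \code{"duration"} or \code{"frequency"}.
#' @param normal_min,normal_max the normal range.
#' @param alpha transition width as a fraction of the range (default 0.25).
#' @param w_min minimum transition half-width (keeps degenerate zero-width
#'   ranges fuzzy); default 0.5 for frequencies, 300 s for durations.
#' @param corners optional list with elements \code{abnormal_minus},
#'   \code{normal}, \code{abnormal_plus}, each \code{c(a, b, c, d)} (NA or
#'   NULL entries mean infinite shoulders).
#' @return List of class \code{dss_variable}.
#' @export
dss_variable <- function(id, label, aspect, normal_min, normal_max,
                         alpha = 0.25, w_min = NULL, corners = NULL) {
  stopifnot(aspect %in% c("duration", "frequency"), normal_min <= normal_max)
  if (is.null(w_min)) w_min <- if (aspect == "frequency") 0.5 else 300
  if (is.null(corners)) {
    w <- max(alpha * (normal_max - normal_min), w_min)
    m <- normal_min; M <- normal_max
    sets <- list(
      `Abnormal-` = fuzzy_trapezoid("Abnormal-", -Inf, -Inf, m - w, m),
      Normal = fuzzy_trapezoid("Normal", m - w, m, M, M + w),
      `Abnormal+` = fuzzy_trapezoid("Abnormal+", M, M + w, Inf, Inf)
    )
  } else {
    corner_set <- function(name, cc) {
      cc <- vapply(cc, function(v) if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v),
                   numeric(1))
      lo <- c(-Inf, -Inf); hi <- c(Inf, Inf)
      cc[1:2][is.na(cc[1:2])] <- lo[is.na(cc[1:2])]
      cc[3:4][is.na(cc[3:4])] <- hi[is.na(cc[3:4])]
      fuzzy_trapezoid(name, cc[1], cc[2], cc[3], cc[4])
    }
    sets <- list(
      `Abnormal-` = corner_set("Abnormal-", corners$abnormal_minus),
      Normal = corner_set("Normal", corners$normal),
      `Abnormal+` = corner_set("Abnormal+", corners$abnormal_plus)
    )
  }
  structure(list(id = id, label = label, aspect = aspect,
                 normal_min = normal_min, normal_max = normal_max,
                 sets = sets),
            class = "dss_variable")
}

#' Fuzzify a crisp value
#'
#' @param value crisp daily duration (s) or frequency (count).
#' @param variable \code{dss_variable}.
#' @return Named numeric degrees for \code{Abnormal-}, \code{Normal},
#'   \code{Abnormal+}.
#' @export
fuzzify_variable <- function(value, variable) {
  vapply(variable$sets, function(s) trapezoid_membership(value, s), numeric(1))
}

#' Evaluate one fuzzy rule
#'
#' A rule is a conjunction (AND, min) of clause groups; each group is a
#' disjunction (OR, max) of \code{(variable, subset)} clauses. Simple all-AND
#' rules are the special case of singleton groups.
#'
#' @param rule list with \code{groups} (list of data.frames with columns
#'   \code{variable}, \code{subset}) and \code{consequent}.
#' @param fuzzified named list: variable id -> named degree vector from
#'   \code{\link{fuzzify_variable}}.
#' @return Activation degree in [0, 1].
#' @export
evaluate_rule <- function(rule, fuzzified) {
  group_degrees <- vapply(rule$groups, function(g) {
    degs <- mapply(function(v, s) {
      f <- fuzzified[[v]]
      if (is.null(f)) stop("rule references unknown variable: ", v)
      unname(f[[s]])
    }, g$variable, g$subset)
    max(degs)
  }, numeric(1))
  min(group_degrees)
}

#' Mamdani inference: clipped consequents aggregated by max
#'
#' Each rule's consequent set is clipped (min) at the rule's activation
#' degree; the rule contributions are aggregated pointwise with max and
#' sampled on a uniform grid over [0, 1].
#'
#' @param activations named numeric vector: output set name -> maximal
#'   activation over the rules concluding on that set.
#' @param output_sets named list of \code{fuzzy_set}s on [0, 1].
#' @param grid_n number of grid samples (>= 2; default 1001).
#' @return List: \code{y} (grid), \code{mu} (aggregated membership),
#'   \code{fired} (FALSE when every activation is 0).
#' @export
mamdani_infer <- function(activations, output_sets, grid_n = 1001L) {
  stopifnot(grid_n >= 2)
  y <- seq(0, 1, length.out = grid_n)
  mu <- numeric(grid_n)
  for (nm in names(output_sets)) {
    act <- if (nm %in% names(activations)) activations[[nm]] else 0
    if (act <= 0) next
    mu <- pmax(mu, pmin(act, trapezoid_membership(y, output_sets[[nm]])))
  }
  list(y = y, mu = mu, fired = any(mu > 0))
}

#' Centroid (center of gravity) defuzzification on a sampled membership
#'
#' @param y grid points.
#' @param mu membership values on the grid; must contain a positive sample.
#' @return y* = sum(y mu) / sum(mu), in [0, 1].
#' @export
defuzzify_centroid <- function(y, mu) {
  if (all(mu <= 0)) stop("no assessment: aggregated membership is zero everywhere")
  sum(y * mu) / sum(mu)
}

#' Read a disease configuration from JSON
#'
#' The document holds the disease name, the decision-support variables
#' (label, aspect, normal range, optional trapezoid corner overrides), the
#' expert rules, the output level sets on [0, 1], the category cutpoints,
#' and the alert names per category. When \code{generate_complete} is true,
#' a complete rule base is generated over every subset combination of the
#' configured variables, with the consequent driven by the number of
#' abnormal clauses: fewer than 2 -> Low, 2-3 -> High, 4 or more -> Very
#' high (the counts are configurable via \code{count_thresholds}). When a
#' complete base is present it drives the assessment alone; the explicit
#' \code{rules} then serve as documented examples of the expert rule style
#' (a partial rule would otherwise double-fire on days whose abnormal-state
#' count already selects a higher level).
#'
#' @param path JSON path, or a pre-parsed list.
#' @return List of class \code{disease_config}.
#' @export
read_disease_config <- function(path) {
  doc <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else path
  variables <- lapply(doc$variables, function(v) {
    dss_variable(id = v$id, label = v$label, aspect = v$aspect,
                 normal_min = v$normal_min, normal_max = v$normal_max,
                 alpha = if (!is.null(doc$alpha)) doc$alpha else 0.25,
                 corners = v$corners)
  })
  names(variables) <- vapply(variables, `[[`, character(1), "id")
  output_sets <- lapply(names(doc$output_sets), function(nm) {
    cc <- as.numeric(doc$output_sets[[nm]])
    fuzzy_trapezoid(nm, cc[1], cc[2], cc[3], cc[4])
  })
  names(output_sets) <- names(doc$output_sets)
  rules <- lapply(doc$rules, function(r) parse_rule(r))
  cfg <- structure(list(
    disease = doc$disease,
    variables = variables,
    rules = rules,
    output_sets = output_sets,
    cutpoints = as.numeric(doc$cutpoints),
    alerts = unlist(doc$alerts),
    grid_n = if (!is.null(doc$grid_n)) as.integer(doc$grid_n) else 1001L,
    count_thresholds = if (!is.null(doc$count_thresholds))
      as.integer(doc$count_thresholds) else c(2L, 4L)
  ), class = "disease_config")
  if (isTRUE(doc$generate_complete)) {
    cfg$complete_base <- generate_count_rules(cfg)
  }
  ok_cons <- vapply(cfg$rules, `[[`, character(1), "consequent")
  stopifnot(all(ok_cons %in% names(cfg$output_sets)))
  cfg
}

# A rule document is {"consequent": ..., "groups": [[{"variable","subset"}...], ...]}
parse_rule <- function(r) {
  groups <- lapply(r$groups, function(g) {
    do.call(rbind, lapply(g, function(cl) {
      data.frame(variable = cl$variable, subset = cl$subset,
                 stringsAsFactors = FALSE)
    }))
  })
  list(consequent = r$consequent, groups = groups)
}

# Complete all-AND rule base: one rule per assignment of a subset to every
# variable; the consequent follows the abnormal-clause count. Stored as a
# subset-index matrix so the whole base evaluates with vectorized min.
generate_count_rules <- function(config) {
  ids <- names(config$variables)
  subset_names <- c("Abnormal-", "Normal", "Abnormal+")
  combos <- as.matrix(expand.grid(rep(list(1:3), length(ids)),
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(combos) <- ids
  n_abn <- rowSums(combos != 2L)  # subset 2 = Normal
  th <- config$count_thresholds
  levels <- names(config$output_sets)
  consequent <- ifelse(n_abn < th[1], levels[1],
                       ifelse(n_abn < th[2], levels[2], levels[3]))
  list(ids = ids, subset_names = subset_names, combos = combos,
       consequent = consequent)
}

# Max activation per output set over the complete base: per rule, min of
# the picked degrees across variables.
evaluate_complete_base <- function(base, fuzzified) {
  deg <- vapply(base$ids, function(v) fuzzified[[v]][base$subset_names],
                numeric(3))  # 3 x k, rows = subsets
  act <- rep(1, nrow(base$combos))
  for (j in seq_along(base$ids)) {
    act <- pmin(act, deg[base$combos[, j], j])
  }
  vapply(split(act, base$consequent), max, numeric(1))
}

#' Assess the disease level for one day's observation
#'
#' Fuzzifies the observation, evaluates every rule (min over AND groups,
#' max within OR groups), aggregates the maximal activation per output set,
#' runs Mamdani inference, and defuzzifies by centroid. The level in [0, 1]
#' maps to a category by the configured cutpoints and to an alert by the
#' category.
#'
#' @param observation named numeric vector/list: variable id -> crisp daily
#'   value (duration total in s, or count).
#' @param config \code{disease_config}.
#' @param day_index optional day label carried through.
#' @return List of class \code{disease_assessment}: \code{day_index},
#'   \code{level}, \code{category}, \code{alert}, \code{activations},
#'   \code{n_abnormal_states}.
#' @export
assess_disease_day <- function(observation, config, day_index = NA_integer_) {
  fuzzified <- lapply(config$variables, function(v) {
    fuzzify_variable(as.numeric(observation[[v$id]]), v)
  })
  activations <- stats::setNames(numeric(length(config$output_sets)),
                                 names(config$output_sets))
  if (!is.null(config$complete_base)) {
    # the complete count-driven base covers every input combination and is
    # the sole driver; partial expert rules would double-fire on days whose
    # abnormal-state count already selects a higher level
    base_act <- evaluate_complete_base(config$complete_base, fuzzified)
    for (nm in names(base_act)) {
      if (base_act[[nm]] > activations[[nm]]) activations[[nm]] <- base_act[[nm]]
    }
  } else {
    for (r in config$rules) {
      a <- evaluate_rule(r, fuzzified)
      if (a > activations[[r$consequent]]) activations[[r$consequent]] <- a
    }
  }
  agg <- mamdani_infer(activations, config$output_sets, config$grid_n)
  if (!agg$fired) stop("no assessment: no rule fired for day ", day_index)
  level <- defuzzify_centroid(agg$y, agg$mu)
  category <- level_category(level, config)
  structure(list(day_index = day_index, level = level, category = category,
                 alert = unname(config$alerts[[category]]),
                 activations = activations,
                 n_abnormal_states = count_abnormal_states(observation, config)),
            class = "disease_assessment")
}

level_category <- function(level, config) {
  nm <- names(config$output_sets)
  cut <- config$cutpoints
  if (level < cut[1]) nm[1] else if (level < cut[2]) nm[2] else nm[3]
}

#' @export
print.disease_assessment <- function(x, ...) {
  cat(sprintf("Day %s: level %.2f -> %s (%s alert), %d abnormal state(s)\n",
              x$day_index, x$level, x$category, x$alert, x$n_abnormal_states))
  invisible(x)
}

#' Daily crisp observation for the decision-support variables
#'
#' Aggregates a day's instances into the crisp inputs the fuzzy system
#' expects: per configured activity, the daily duration total in seconds
#' and the daily occurrence count (both 0 when the activity is absent).
#'
#' @param day_instances \code{adl_instances} rows of one day (source labels).
#' @param config \code{disease_config}.
#' @return Named numeric vector keyed by variable id.
#' @export
daily_observation <- function(day_instances, config) {
  out <- numeric(0)
  for (v in config$variables) {
    rows <- day_instances$label == v$label
    out[[v$id]] <- if (v$aspect == "duration") {
      sum(day_instances$duration[rows])
    } else {
      sum(rows)
    }
  }
  out
}

#' Build a disease configuration from a learned profile
#'
#' Normal ranges come from the profile's baseline daily aggregates
#' (duration totals and counts per activity); trapezoid corners use the
#' default geometry; rules are the complete count-driven base.
#'
#' @param profile \code{adl_profile}.
#' @param disease disease name.
#' @param labels activities to include; default the four disease-relevant
#'   ones present in the profile.
#' @param alpha transition width fraction (default 0.25).
#' @return \code{disease_config}.
#' @export
disease_config_from_profile <- function(profile, disease = "suspected",
                                        labels = NULL, alpha = 0.25) {
  dr <- profile$daily_ranges
  if (is.null(labels)) {
    labels <- intersect(c("leaving_home", "going_to_toilet", "eating",
                          "sleeping"), dr$label)
  }
  vars <- list()
  for (lab in labels) {
    row <- dr[dr$label == lab, ]
    vars[[length(vars) + 1L]] <- list(
      id = paste0(lab, ".duration"), label = lab, aspect = "duration",
      normal_min = row$dur_min, normal_max = row$dur_max)
    vars[[length(vars) + 1L]] <- list(
      id = paste0(lab, ".frequency"), label = lab, aspect = "frequency",
      normal_min = row$freq_min, normal_max = row$freq_max)
  }
  read_disease_config(list(
    disease = disease, alpha = alpha, variables = vars, rules = list(),
    generate_complete = TRUE,
    output_sets = list(Low = c(0, 0, 0.2, 0.4), High = c(0.2, 0.4, 0.6, 0.8),
                       `Very high` = c(0.6, 0.8, 1, 1)),
    cutpoints = c(1 / 3, 2 / 3),
    alerts = list(Low = "Minor", High = "Important", `Very high` = "Major")
  ))
}

#' Path to the shipped gastrointestinal example configuration
#'
#' A reference configuration for a gastrointestinal episode: four
#' activities (leaving home, going to toilet, eating, sleeping) with
#' expert-style normal ranges, per-variable trapezoid corners calibrated on
#' the two worked fuzzification anchors (leaving-home duration 4600 s ->
#' Abnormal- 0.3 / Normal 0.1; sleeping duration 30,000 s -> Abnormal- 0.2 /
#' Normal 0.6), three illustrative expert rules, and the complete
#' count-driven rule base.
#'
#' @return File path inside the installed package.
#' @export
gastro_config_path <- function() {
  system.file("extdata", "gastro.json", package = "adlmonitor", mustWork = TRUE)
}
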