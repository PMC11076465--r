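#' Discriminability range of a task measure
#'
#' The greatest absolute standardized difference between any patient
#' group and the controls, so a task is retained if it is sensitive to
#' either clinical group.
#'
#' @param contrasts a `cb_contrast` tibble of patient-vs-control rows for
#'   one measure (from [group_contrast()]).
#' @return Non-negative scalar.
#' @export
#' @examples
#' # PD -0.7, RBD -0.3 vs control -> 0.7
discriminability_range <- function(contrasts) {
  if (nrow(contrasts) < 1) {
    cb_abort("no patient-group contrasts supplied", "cb_selection_error")
  }
  max(abs(contrasts$smd))
}

#' Device sensitivity of a measure in a normative sample
#'
#' Absolute mean difference between phone and computer users on adjusted
#' scores, the two device classes that differ most in input hardware.
#'
#' @param adjusted a `cb_adjusted` built from a normative sample (its
#'   participants table must carry `device`).
#' @param measure_id measure to assess.
#' @param devices the two device levels contrasted.
#' @return Non-negative scalar.
#' @export
device_sensitivity <- function(adjusted, measure_id,
                               devices = c("phone", "computer")) {
  dev <- as.character(adjusted$participants$device)
  y <- adjusted$scores[, measure_id]
  counts <- vapply(devices, function(d) sum(dev == d & !is.na(y)), 0L)
  if (any(counts < 2)) {
    cb_abort(paste0("device group(s) absent or too small: ",
                    paste(devices[counts < 2], collapse = ", ")),
             "cb_selection_error")
  }
  abs(mean(y[dev == devices[1]], na.rm = TRUE) -
        mean(y[dev == devices[2]], na.rm = TRUE))
}

#' Quadrant classification of a task
#'
#' Tasks plotted by group discriminability (y) against device sensitivity
#' (x) fall into four quadrants; the optimal quadrant has medium-or-better
#' group discrimination with small-to-negligible device discrimination.
#'
#' @param disc discriminability range (SD units).
#' @param dev device sensitivity (SD units).
#' @param disc_min minimum discriminability for the optimal quadrant
#'   (default 0.5, a medium effect).
#' @param dev_max maximum device sensitivity (default 0.2, a small
#'   effect).
#' @return One of `"optimal"`, `"low_discrimination"`,
#'   `"device_sensitive"`, `"low_and_device_sensitive"`.
#' @export
classify_quadrant <- function(disc, dev, disc_min = 0.5, dev_max = 0.2) {
  if (disc >= disc_min && dev <= dev_max) "optimal"
  else if (disc >= disc_min) "device_sensitive"
  else if (dev <= dev_max) "low_discrimination"
  else "low_and_device_sensitive"
}

#' Selection rules
#'
#' @param disc_min,dev_max quadrant thresholds (see
#'   [classify_quadrant()]).
#' @param discreteness_min minimum gap between a measure's top two
#'   absolute rotated loadings for a "discrete" factor assignment.
#' @param instruction_overhead_min per-task instruction time added when
#'   estimating battery duration.
#' @return List of class `cb_selection_rules`.
#' @export
selection_rules <- function(disc_min = 0.5, dev_max = 0.2,
                            discreteness_min = 0.1,
                            instruction_overhead_min = 0.45) {
  if (disc_min < 0 || dev_max < 0 || discreteness_min < 0) {
    cb_abort("selection thresholds must be nonnegative", "cb_config_error")
  }
  structure(list(disc_min = disc_min, dev_max = dev_max,
                 discreteness_min = discreteness_min,
                 instruction_overhead_min = instruction_overhead_min),
            class = "cb_selection_rules")
}

#' Per-task metrics feeding the battery selection
#'
#' @param task_id task identifiers.
#' @param discriminability per-task discriminability range.
#' @param device_sensitivity per-task device sensitivity.
#' @param solution a rotated `cb_factor_solution` over the primary
#'   measures, used for dominant factor and discreteness.
#' @param rules a [selection_rules()].
#' @return A `cb_task_metrics` tibble: task_id, discriminability,
#'   device_sensitivity, dominant_factor, discreteness, discrete,
#'   quadrant.
#' @export
task_metrics <- function(task_id, discriminability, device_sensitivity,
                         solution, rules = selection_rules()) {
  dom <- lapply(paste0(task_id, ".primary"), function(m) {
    dominant_factor(solution, m, threshold = rules$discreteness_min)
  })
  out <- tibble::tibble(
    task_id = task_id,
    discriminability = discriminability,
    device_sensitivity = device_sensitivity,
    dominant_factor = vapply(dom, `[[`, "", "factor"),
    discreteness = vapply(dom, `[[`, 0, "discreteness"),
    discrete = vapply(dom, `[[`, TRUE, "discrete"),
    quadrant = mapply(classify_quadrant, discriminability,
                      device_sensitivity,
                      MoreArgs = list(disc_min = rules$disc_min,
                                      dev_max = rules$dev_max)))
  class(out) <- c("cb_task_metrics", class(out))
  out
}

#' Select the final assessment battery
#'
#' Applies the published selection procedure: a task is included when it
#' sits in the optimal quadrant (discriminability at least `disc_min`,
#' device sensitivity at most `dev_max`) and loads discretely on a single
#' factor. Exclusion reasons are, in order of precedence: device
#' sensitivity, low discriminability, then non-discrete loading; a
#' non-discrete task is additionally marked redundant when another task
#' with the same dominant factor discriminates better. Excluded speeded
#' tasks lose no latency information because reaction times are recorded
#' as secondary scores of every retained task; the report carries this
#' note.
#'
#' @param metrics a `cb_task_metrics` covering every candidate task.
#' @param rules a [selection_rules()].
#' @param catalog a [task_catalog()] (battery slots and durations).
#' @return A `cb_selection_report`: `decisions` tibble (task_id, metrics,
#'   decision, reason), `battery` (included battery_task slots),
#'   `duration_min` (summed task time plus per-task instruction
#'   overhead), `rules`, `notes`.
#' @export
select_battery <- function(metrics, rules = selection_rules(),
                           catalog = task_catalog()) {
  missing_tasks <- setdiff(catalog$task_id, metrics$task_id)
  if (length(missing_tasks)) {
    cb_abort(paste0("metrics missing for task(s): ",
                    paste(missing_tasks, collapse = ", ")),
             "cb_selection_error")
  }
  metrics <- metrics[order(metrics$task_id), ]
  # derive quadrant and discreteness from the metrics under these rules,
  # so thresholds supplied here always govern the decision
  metrics$quadrant <- mapply(classify_quadrant, metrics$discriminability,
                             metrics$device_sensitivity,
                             MoreArgs = list(disc_min = rules$disc_min,
                                             dev_max = rules$dev_max))
  metrics$discrete <- metrics$discreteness >= rules$discreteness_min
  include <- metrics$quadrant == "optimal" & metrics$discrete
  reason <- rep(NA_character_, nrow(metrics))
  dev_bad <- metrics$device_sensitivity > rules$dev_max
  disc_bad <- metrics$discriminability < rules$disc_min
  reason[!include & dev_bad] <- "device_sensitive"
  reason[!include & !dev_bad & disc_bad] <- "low_discriminability"
  reason[!include & !dev_bad & !disc_bad] <- "non_discrete_loading"
  # redundancy: a non-discrete task whose factor is better covered
  redundant <- vapply(seq_len(nrow(metrics)), function(i) {
    if (metrics$discrete[i]) return(FALSE)
    same <- metrics$dominant_factor == metrics$dominant_factor[i]
    any(same & metrics$discriminability > metrics$discriminability[i])
  }, TRUE)

  decisions <- metrics
  decisions$decision <- ifelse(include, "include", "exclude")
  decisions$reason <- reason
  decisions$redundant_with_factor <- redundant & !include

  rows <- match(decisions$task_id, catalog$task_id)
  decisions$battery_task <- catalog$battery_task[rows]
  inc <- decisions[decisions$decision == "include", ]
  battery <- sort(unique(inc$battery_task))
  duration <- sum(catalog$duration_min[catalog$task_id %in% inc$task_id]) +
    rules$instruction_overhead_min * length(battery)
  notes <- paste(
    "Reaction times are recorded for every retained task as secondary",
    "scores, so excluding speeded tasks discards no latency information.")
  if (!nrow(inc)) {
    warn("no task meets the selection thresholds; battery is empty")
  }
  structure(list(decisions = decisions, battery = battery,
                 duration_min = duration, rules = rules, notes = notes),
            class = "cb_selection_report")
}

#' @export
print.cb_selection_report <- function(x, ...) {
  cat(sprintf("<cb_selection_report> %d tasks included (~%.1f min): %s\n",
              length(x$battery), x$duration_min,
              paste(x$battery, collapse = ", ")))
  invisible(x)
}

#' Deterministic task-metrics fixture matching the published pattern
#'
#' A synthetic reference grid for exercising the selection procedure: the
#' discriminability and device-sensitivity values are engineered (not
#' estimated) to reproduce the published quadrant layout - recommended
#' tasks in the optimal quadrant, two planning/matching tasks with low
#' group discrimination, three speeded/visual tasks with high device
#' sensitivity, and one memory task with a non-discrete loading pattern.
#' Dominant factors and discreteness come from the generator's default
#' loading structure.
#'
#' @param rules a [selection_rules()].
#' @return A `cb_task_metrics` tibble.
#' @export
paper_pattern_metrics <- function(rules = selection_rules()) {
  config <- generator_config()
  catalog <- config$catalog
  prim <- catalog_measures(catalog, "primary")
  sol <- structure(list(loadings = config$loadings[prim, ],
                        n_factors = 5), class = "cb_factor_solution")
  disc <- c(
    target_detection = 0.55, srt = 0.62, recognition_immediate = 0.65,
    recognition_delayed = 0.70, digit_span = 0.42, spatial_span = 0.35,
    pal = 0.55, card_pairs = 0.25, manipulations_2d = 0.38,
    four_towers = 0.40, picture_completion = 0.52,
    emotional_discrimination = 0.52, blocks = 0.54, tower_of_london = 0.30,
    switching_stroop = 0.60, trail_making = 0.60, verbal_analogies = 0.62,
    word_definitions = 0.70, motor_control = 0.55)
  dev <- c(
    target_detection = 0.06, srt = 0.35, recognition_immediate = 0.04,
    recognition_delayed = 0.04, digit_span = 0.05, spatial_span = 0.05,
    pal = 0.06, card_pairs = 0.05, manipulations_2d = 0.08,
    four_towers = 0.08, picture_completion = 0.25,
    emotional_discrimination = 0.05, blocks = 0.07, tower_of_london = 0.06,
    switching_stroop = 0.05, trail_making = 0.10, verbal_analogies = 0.04,
    word_definitions = 0.03, motor_control = 0.30)
  ids <- catalog$task_id
  task_metrics(ids, unname(disc[ids]), unname(dev[ids]), sol, rules)
}
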