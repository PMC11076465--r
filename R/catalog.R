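#' Default task catalog for the 19-task candidate battery
#'
#' Returns the catalog of candidate tasks evaluated for the remote
#' assessment battery: two assessment-day batteries of short browser tasks,
#' each yielding a primary summary score (response accuracy, or response
#' latency for the three speeded tasks) and, for accuracy tasks, a
#' secondary latency score. Immediate and delayed word recognition are two
#' catalog rows sharing one battery slot (`battery_task`), so the final
#' recommended battery counts 8 tasks across 9 scored measures.
#'
#' @details Columns:
#' \describe{
#'   \item{task_id}{unique short name.}
#'   \item{battery}{assessment day, 1 or 2.}
#'   \item{battery_task}{slot identifier; equals `task_id` except for the
#'     two recognition-memory rows which share one slot.}
#'   \item{primary_kind}{`"accuracy"` or `"latency"` for the primary score.}
#'   \item{has_secondary}{whether a secondary latency score is recorded
#'     (true for accuracy-primary tasks; speeded tasks have latency as
#'     their primary score).}
#'   \item{operational_complexity}{1-3, simple responding through complex
#'     reasoning.}
#'   \item{duration_min}{task run time in minutes, excluding instructions.}
#'   \item{final_battery_member}{whether the task is in the recommended
#'     brief battery.}
#'   \item{exclusion_reason}{for non-members, one of
#'     `low_discriminability`, `device_sensitive`, `non_discrete_loading`,
#'     `redundant`; `NA` for members.}
#' }
#'
#' @return A tibble of class `cb_catalog` with one row per task.
#' @export
#' @examples
#' cat19 <- task_catalog()
#' sum(cat19$final_battery_member)          # 9 rows ...
#' length(unique(cat19$battery_task[cat19$final_battery_member]))  # 8 tasks
task_catalog <- function() {
  x <- tibble::tribble(
    ~task_id, ~battery, ~battery_task, ~primary_kind, ~operational_complexity,
      ~duration_min, ~final_battery_member, ~exclusion_reason,
    "motor_control",            1L, "motor_control",            "latency",  1L, 1.0, FALSE, "device_sensitive",
    "recognition_immediate",    1L, "word_recognition_memory",  "accuracy", 1L, 1.0, TRUE,  NA,
    "target_detection",         1L, "target_detection",         "accuracy", 1L, 2.0, TRUE,  NA,
    "emotional_discrimination", 1L, "emotional_discrimination", "accuracy", 1L, 1.5, TRUE,  NA,
    "manipulations_2d",         1L, "manipulations_2d",         "accuracy", 1L, 1.5, FALSE, "low_discriminability",
    "digit_span",               1L, "digit_span",               "accuracy", 2L, 2.0, FALSE, "low_discriminability",
    "spatial_span",             1L, "spatial_span",             "accuracy", 2L, 2.0, FALSE, "low_discriminability",
    "blocks",                   1L, "blocks",                   "accuracy", 3L, 1.0, TRUE,  NA,
    "tower_of_london",          1L, "tower_of_london",          "accuracy", 3L, 3.0, FALSE, "low_discriminability",
    "word_definitions",         1L, "word_definitions",         "accuracy", 3L, 4.0, TRUE,  NA,
    "srt",                      2L, "srt",                      "latency",  1L, 1.0, FALSE, "device_sensitive",
    "trail_making",             2L, "trail_making",             "latency",  1L, 2.0, TRUE,  NA,
    "pal",                      2L, "pal",                      "accuracy", 2L, 2.5, FALSE, "non_discrete_loading",
    "switching_stroop",         2L, "switching_stroop",         "accuracy", 3L, 1.5, TRUE,  NA,
    "picture_completion",       2L, "picture_completion",       "accuracy", 3L, 1.5, FALSE, "device_sensitive",
    "card_pairs",               2L, "card_pairs",               "accuracy", 3L, 2.0, FALSE, "low_discriminability",
    "four_towers",              2L, "four_towers",              "accuracy", 3L, 2.0, FALSE, "low_discriminability",
    "verbal_analogies",         2L, "verbal_analogies",         "accuracy", 3L, 3.0, TRUE,  NA,
    "recognition_delayed",      2L, "word_recognition_memory",  "accuracy", 2L, 0.5, TRUE,  NA
  )
  x$has_secondary <- x$primary_kind == "accuracy"
  class(x) <- c("cb_catalog", class(x))
  validate_catalog(x)
  x
}

validate_catalog <- function(catalog) {
  if (nrow(catalog) != length(unique(catalog$task_id))) {
    cb_abort("task_ids must be unique", "cb_catalog_error")
  }
  bad <- !catalog$final_battery_member & is.na(catalog$exclusion_reason)
  if (any(bad)) {
    cb_abort(paste0("excluded tasks without a reason: ",
                    paste(catalog$task_id[bad], collapse = ", ")),
             "cb_catalog_error")
  }
  reasons <- stats::na.omit(catalog$exclusion_reason)
  ok <- reasons %in% c("low_discriminability", "device_sensitive",
                       "non_discrete_loading", "redundant")
  if (!all(ok)) cb_abort("unknown exclusion reason", "cb_catalog_error")
  invisible(catalog)
}

#' Measure identifiers defined by a catalog
#'
#' Task score columns are named `<task_id>.primary` and, for accuracy
#' tasks, `<task_id>.secondary`; the secondary score is always a latency.
#'
#' @param catalog a [task_catalog()].
#' @param which `"all"`, `"primary"`, `"secondary"`, `"accuracy"` (accuracy
#'   primaries) or `"latency"` (latency primaries plus all secondaries).
#' @return Character vector of measure ids.
#' @export
catalog_measures <- function(catalog, which = "all") {
  prim <- paste0(catalog$task_id, ".primary")
  sec <- paste0(catalog$task_id[catalog$has_secondary], ".secondary")
  switch(which,
    all = c(prim, sec),
    primary = prim,
    secondary = sec,
    accuracy = prim[catalog$primary_kind == "accuracy"],
    latency = c(prim[catalog$primary_kind == "latency"], sec),
    cb_abort(paste0("unknown measure set: ", which), "cb_catalog_error")
  )
}

#' Score orientation for a measure
#'
#' @param catalog a [task_catalog()].
#' @param measure_id measure id such as `"blocks.primary"`.
#' @return `"higher_better"` (accuracy) or `"lower_better"` (latency).
#' @export
measure_direction <- function(catalog, measure_id) {
  kind <- measure_kind(catalog, measure_id)
  ifelse(kind == "accuracy", "higher_better", "lower_better")
}

#' @rdname measure_direction
#' @return `measure_kind()` returns `"accuracy"` or `"latency"`.
#' @export
measure_kind <- function(catalog, measure_id) {
  parts <- strsplit(measure_id, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2 || !p[1] %in% catalog$task_id ||
        !p[2] %in% c("primary", "secondary")) {
      cb_abort(paste0("unknown measure id: ", paste(p, collapse = ".")),
               "cb_measure_error")
    }
    if (p[2] == "secondary") "latency"
    else catalog$primary_kind[catalog$task_id == p[1]]
  }, character(1))
}
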