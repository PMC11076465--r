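#' Load a wide cohort table from CSV
#'
#' One row per participant: group label, sociodemographics, assessment
#' device, clinical scale scores, and task scores in columns named
#' `<task_id>.primary` / `<task_id>.secondary`. Empty strings are treated
#' as missing. Categorical columns are coerced to their fixed level sets;
#' unknown columns are kept untouched.
#'
#' @param path CSV file path.
#' @param catalog a [task_catalog()] used to resolve task score columns.
#' @param latency_oriented whether latency scores in the file are already
#'   oriented high = good (the package's storage convention; pass `FALSE`
#'   for raw timing scores where lower is better).
#' @return A tibble of class `cb_cohort` with the catalog attached as an
#'   attribute.
#' @export
load_cohort <- function(path, catalog = task_catalog(),
                        latency_oriented = TRUE) {
  if (!file.exists(path)) {
    cb_abort(paste0("cohort file does not exist: ", path), "cb_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  cohort <- as_cohort(raw, catalog, latency_oriented = latency_oriented)
  inform(sprintf("loaded cohort: %d participants, %d columns",
                 nrow(cohort), ncol(cohort)))
  cohort
}

#' Construct a cohort table from a data frame
#'
#' @param x data frame in the wide cohort layout.
#' @param catalog a [task_catalog()].
#' @inheritParams load_cohort
#' @return A `cb_cohort` tibble.
#' @export
as_cohort <- function(x, catalog = task_catalog(),
                      latency_oriented = TRUE) {
  mandatory <- c("participant_id", "group", "age_years", "sex",
                 "education_band")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    cb_abort(paste0("missing mandatory columns: ",
                    paste(missing_cols, collapse = ", ")),
             "cb_missing_columns", columns = missing_cols)
  }
  x <- tibble::as_tibble(x)
  x$group <- check_levels(x$group, GROUP_LEVELS, "group")
  x$sex <- check_levels(x$sex, SEX_LEVELS, "sex")
  x$education_band <- check_levels(x$education_band, EDUCATION_LEVELS,
                                   "education_band")
  if (!"age_decade" %in% names(x)) {
    x$age_decade <- paste0(floor(x$age_years / 10) * 10, "s")
  }
  x$age_decade <- check_levels(x$age_decade, DECADE_LEVELS, "age_decade")
  if ("device" %in% names(x)) {
    x$device <- check_levels(x$device, DEVICE_LEVELS, "device")
  }
  if ("rbdsq" %in% names(x)) x$probable_rbd <- !is.na(x$rbdsq) & x$rbdsq > 6
  known <- intersect(catalog_measures(catalog), names(x))
  for (m in known) x[[m]] <- as.numeric(x[[m]])
  attr(x, "catalog") <- catalog
  if (is.null(attr(x, "latency_oriented"))) {
    attr(x, "latency_oriented") <- latency_oriented
  }
  class(x) <- c("cb_cohort", setdiff(class(x), "cb_cohort"))
  x
}

check_levels <- function(values, levels, name) {
  bad <- which(!is.na(values) & !values %in% levels)
  if (length(bad)) {
    cb_abort(sprintf("column '%s' has unknown value '%s' in row %d",
                     name, values[bad[1]], bad[1]),
             "cb_bad_level", column = name, row = bad[1],
             value = values[bad[1]])
  }
  factor(values, levels = levels)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: values and missingness round-trip exactly
#' (missing cells are written as empty strings).
#'
#' @param cohort a `cb_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Diagnostic checks on a loaded cohort
#'
#' Flags (without erroring): age-decade labels inconsistent with age,
#' out-of-range scale scores, per-task completion counts and the
#' composite-eligible subset (participants with all primary task scores
#' present).
#'
#' @param cohort a `cb_cohort`.
#' @param catalog a [task_catalog()].
#' @return A list with `issues` (tibble: participant_id, check, detail),
#'   `completion` (tibble: measure_id, n_complete) and
#'   `composite_eligible` (tibble: group, n_complete_all_tasks).
#' @export
validate_cohort <- function(cohort, catalog = task_catalog()) {
  issues <- list()
  expected <- paste0(floor(cohort$age_years / 10) * 10, "s")
  bad_dec <- which(!is.na(cohort$age_decade) & !is.na(cohort$age_years) &
                     as.character(cohort$age_decade) != expected)
  for (i in bad_dec) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      participant_id = as.character(cohort$participant_id[i]),
      check = "age_decade_mismatch",
      detail = sprintf("age %g tagged %s", cohort$age_years[i],
                       cohort$age_decade[i]))
  }
  scale_ranges <- list(moca_total.baseline = c(0, 30),
                       moca_total.assessment = c(0, 30),
                       mmse_total.baseline = c(0, 30),
                       rbdsq = c(0, 13))
  for (col in intersect(names(scale_ranges), names(cohort))) {
    rng <- scale_ranges[[col]]
    bad <- which(!is.na(cohort[[col]]) &
                   (cohort[[col]] < rng[1] | cohort[[col]] > rng[2]))
    for (i in bad) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        participant_id = as.character(cohort$participant_id[i]),
        check = "scale_out_of_range",
        detail = sprintf("%s = %g outside [%g, %g]", col, cohort[[col]][i],
                         rng[1], rng[2]))
    }
  }
  prim <- intersect(catalog_measures(catalog, "primary"), names(cohort))
  completion <- tibble::tibble(
    measure_id = prim,
    n_complete = vapply(prim, function(m) sum(!is.na(cohort[[m]])), 0L))
  complete_all <- if (length(prim)) {
    stats::complete.cases(cohort[, prim, drop = FALSE])
  } else rep(TRUE, nrow(cohort))
  eligible <- dplyr::count(
    tibble::tibble(group = cohort$group[complete_all]),
    .data$group, name = "n_complete_all_tasks")
  list(
    issues = if (length(issues)) dplyr::bind_rows(issues) else
      tibble::tibble(participant_id = character(), check = character(),
                     detail = character()),
    completion = completion,
    composite_eligible = eligible)
}

#' Scale scores in long form
#'
#' Clinical scale scores collected at two timepoints (cohort enrolment
#' `baseline` and the visit closest to the online `assessment`) are stored
#' as wide `<scale>.<timepoint>` columns; this accessor pivots them to a
#' long table with a timepoint tag.
#'
#' @param cohort a `cb_cohort`.
#' @return Tibble with participant_id, scale, timepoint, value.
#' @export
scale_scores_long <- function(cohort) {
  cols <- grep("^(moca_total|mmse_total)\\.(baseline|assessment)$",
               names(cohort), value = TRUE)
  out <- tidyr::pivot_longer(
    cohort[, c("participant_id", cols)], dplyr::all_of(cols),
    names_to = c("scale", "timepoint"), names_sep = "\\.")
  out
}
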