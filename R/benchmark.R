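#' Adjust a supervised scale score like a task measure
#'
#' Applies the same confound model + rank-normalization used for task
#' scores to a clinical scale column (e.g. the MoCA total), so scale and
#' task scores are compared on the same footing.
#'
#' @param cohort a `cb_cohort`.
#' @param scale_col column name, e.g. `"moca_total.assessment"`.
#' @param covariates confound terms.
#' @param offset rank-INT offset.
#' @return A `cb_adjusted` with a single column named after `scale_col`.
#' @export
adjust_scale <- function(cohort, scale_col,
                         covariates = c("age_decade", "sex",
                                        "education_band"),
                         offset = 3 / 8) {
  model <- fit_confound_model(cohort[[scale_col]], cohort,
                              terms = covariates)
  res <- residualize(model, cohort, cohort[[scale_col]])
  z <- rank_inverse_normal(res, offset = offset)
  scores <- matrix(z, ncol = 1,
                   dimnames = list(as.character(cohort$participant_id),
                                   scale_col))
  out <- adjusted_from_matrix(
    scores, cohort[, intersect(
      c("participant_id", "group", "age_decade", "sex", "education_band",
        "device", "probable_rbd"), names(cohort))],
    attr(cohort, "catalog") %n% task_catalog())
  out$models <- stats::setNames(list(model), scale_col)
  out$covariates <- covariates
  out
}

#' Predict a supervised scale from selected task scores
#'
#' Multiple OLS of the adjusted scale on the adjusted scores of the
#' recommended battery tasks; reports fit R-squared, the overall F-test
#' p-value and coefficients.
#'
#' @param adjusted a `cb_adjusted` holding task scores.
#' @param measures predictor measure ids.
#' @param scale_values adjusted scale values aligned with
#'   `adjusted$participants`.
#' @param condition_cap condition-number threshold above which a
#'   collinearity warning is issued.
#' @return List: `r_squared`, `p_value`, `coefficients`, `n`.
#' @export
predict_scale_from_tasks <- function(adjusted, measures, scale_values,
                                     condition_cap = 1e6) {
  x <- adjusted$scores[, measures, drop = FALSE]
  keep <- stats::complete.cases(x) & !is.na(scale_values)
  if (sum(keep) < length(measures) + 2) {
    cb_abort(sprintf("%d complete cases for %d predictors; need >= %d",
                     sum(keep), length(measures), length(measures) + 2),
             "cb_benchmark_error")
  }
  xm <- x[keep, , drop = FALSE]
  sv <- svd(scale(xm), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || (sv[1] / sv[length(sv)])^2 > condition_cap) {
    warn("task predictors are near-collinear; coefficients are unstable")
  }
  fit <- stats::lm(scale_values[keep] ~ xm)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       coefficients = stats::setNames(coef(fit),
                                      c("(Intercept)", measures)),
       n = sum(keep))
}

#' Pearson correlations between each task measure and a scale
#'
#' Pairwise-complete correlations with two-sided p-values; measures with
#' fewer than 3 paired observations are skipped with a warning.
#'
#' @param adjusted a `cb_adjusted`.
#' @param scale_values adjusted scale values aligned with participants.
#' @param measures measure ids (default all).
#' @return Tibble: measure_id, r, p_value, n.
#' @export
task_scale_correlations <- function(adjusted, scale_values,
                                    measures = NULL) {
  measures <- measures %n% colnames(adjusted$scores)
  rows <- lapply(measures, function(m) {
    y <- adjusted$scores[, m]
    keep <- !is.na(y) & !is.na(scale_values)
    if (sum(keep) < 3) {
      warn(sprintf("measure %s skipped: only %d paired observations", m,
                   sum(keep)))
      return(NULL)
    }
    ct <- stats::cor.test(y[keep], scale_values[keep])
    tibble::tibble(measure_id = m, r = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(keep))
  })
  dplyr::bind_rows(rows)
}

#' Predict the battery composite from scale subscales
#'
#' OLS of the composite on the categorical section scores of a supervised
#' scale (each section entered as a factor). Sparse section levels with a
#' single observation are merged into the nearest level.
#'
#' @param composite a `cb_composites`.
#' @param subscales data frame of integer section scores, rows aligned
#'   with the cohort the composite was built from and carrying
#'   `participant_id`.
#' @param min_level_n levels rarer than this are merged with the nearest
#'   score level.
#' @return List: `r_squared`, `p_value`, `n`, `n_predictors`.
#' @export
predict_composite_from_subscales <- function(composite, subscales,
                                             min_level_n = 2) {
  idx <- match(composite$participant_id, subscales$participant_id)
  sub <- subscales[idx, setdiff(names(subscales), "participant_id"),
                   drop = FALSE]
  keep <- stats::complete.cases(sub) & !is.na(composite$score)
  sub <- sub[keep, , drop = FALSE]
  y <- composite$score[keep]
  dat <- lapply(sub, function(col) {
    merged <- merge_sparse_levels(col, min_level_n)
    factor(merged)
  })
  dat <- as.data.frame(dat)
  dat <- dat[, vapply(dat, nlevels, 0L) > 1, drop = FALSE]
  if (!ncol(dat)) {
    cb_abort("no subscale varies; cannot fit", "cb_benchmark_error")
  }
  dat$.y <- y
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       n = length(y),
       n_predictors = sum(vapply(dat[setdiff(names(dat), ".y")],
                                 nlevels, 0L) - 1L))
}

merge_sparse_levels <- function(x, min_n) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  for (v in vals[tab < min_n]) {
    others <- vals[vals != v & tab[as.character(vals)] >= min_n]
    if (!length(others)) next
    nearest <- others[which.min(abs(others - v))]
    x[x == v] <- nearest
    warn(sprintf("subscale level %g merged into %g (n < %d)", v, nearest,
                 min_n))
  }
  x
}

#' Group discriminability of a supervised scale
#'
#' The scale analogue of the per-measure group contrast: how far apart
#' the clinical groups sit on the adjusted scale score.
#'
#' @param adjusted_scale a `cb_adjusted` from [adjust_scale()].
#' @param groups,reference as in [group_contrast()].
#' @return A `cb_contrast` tibble.
#' @export
scale_group_discriminability <- function(adjusted_scale, groups = NULL,
                                         reference = "control") {
  group_contrast(adjusted_scale, colnames(adjusted_scale$scores)[1],
                 groups = groups, reference = reference)
}

#' Paired change test between two scale timepoints
#'
#' Per-group paired two-sided t-test of follow-up minus baseline; rows
#' missing either timepoint are dropped with a count.
#'
#' @param baseline,followup numeric vectors for the same participants.
#' @param group group labels.
#' @param interval_years optional per-participant assessment interval,
#'   summarized alongside.
#' @return Tibble: group, statistic, p_value, mean_change, n_pairs,
#'   n_dropped, mean_interval, sd_interval.
#' @export
paired_change_test <- function(baseline, followup, group,
                               interval_years = NULL) {
  out <- lapply(unique(as.character(group)), function(g) {
    rows <- as.character(group) == g
    b <- baseline[rows]
    f <- followup[rows]
    ok <- !is.na(b) & !is.na(f)
    if (sum(ok) < 2) {
      cb_abort(sprintf("group %s has %d complete pairs; need >= 2", g,
                       sum(ok)), "cb_benchmark_error")
    }
    d <- f[ok] - b[ok]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(f[ok], b[ok], paired = TRUE)
    }
    iv <- if (!is.null(interval_years)) interval_years[rows][ok]
    tibble::tibble(
      group = g, statistic = unname(tt$statistic), p_value = tt$p.value,
      mean_change = mean(d), n_pairs = sum(ok), n_dropped = sum(!ok),
      mean_interval = if (is.null(iv)) NA_real_ else mean(iv),
      sd_interval = if (is.null(iv)) NA_real_ else stats::sd(iv))
  })
  dplyr::bind_rows(out)
}

#' Benchmark the battery against a supervised scale
#'
#' Bundles the convergence/divergence analyses: regression of the
#' adjusted scale on the recommended tasks, per-measure correlations with
#' the scale, prediction of the battery composite from scale subscales,
#' scale group discriminability, the paired baseline-to-assessment change
#' test, and the composite-scale correlation (reported for both adjusted
#' and raw scale scores).
#'
#' @param cohort a `cb_cohort` with scale columns.
#' @param adjusted a `cb_adjusted` of the task measures.
#' @param composite a `cb_composites` for the recommended battery.
#' @param battery_measures measure ids of the recommended battery.
#' @param scale `"moca"` or `"mmse"`.
#' @return A `cb_benchmark_report` list.
#' @export
benchmark_scale <- function(cohort, adjusted, composite, battery_measures,
                            scale = c("moca", "mmse")) {
  scale <- match.arg(scale)
  scale_col <- if (scale == "moca") "moca_total.assessment" else
    "mmse_total.baseline"
  adj_scale <- adjust_scale(cohort, scale_col)
  sv <- adj_scale$scores[, 1]
  fit_tasks <- predict_scale_from_tasks(adjusted, battery_measures, sv)
  corrs <- task_scale_correlations(adjusted, sv,
                                   measures = battery_measures)
  idx <- match(composite$participant_id, cohort$participant_id)
  comp_adj <- stats::cor.test(composite$score, sv[idx])
  comp_raw <- stats::cor.test(composite$score, cohort[[scale_col]][idx])
  subs_cols <- grep("^moca_sub", names(cohort), value = TRUE)
  fit_subscales <- if (scale == "moca" && length(subs_cols)) {
    predict_composite_from_subscales(
      composite, cohort[, c("participant_id", subs_cols)])
  }
  disc <- scale_group_discriminability(adj_scale)
  change <- if (scale == "moca") {
    paired_change_test(cohort$moca_total.baseline,
                       cohort$moca_total.assessment, cohort$group)
  }
  structure(list(
    scale = scale, scale_column = scale_col,
    scale_model_r_squared = adj_scale$models[[1]]$r_squared,
    scale_from_tasks = fit_tasks,
    task_correlations = corrs,
    composite_scale_r = unname(comp_adj$estimate),
    composite_scale_p = comp_adj$p.value,
    composite_raw_scale_r = unname(comp_raw$estimate),
    composite_from_subscales = fit_subscales,
    scale_discriminability = disc,
    paired_change = change), class = "cb_benchmark_report")
}
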