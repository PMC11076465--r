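#' Fit a sociodemographic confound model for one measure
#'
#' Ordinary least squares of a score on age decade (categorical, allowing
#' non-linear age effects), sex, and education band, on the non-missing
#' rows. The residuals of this model are the quantity carried into
#' normalization and contrast estimation.
#'
#' @param values numeric vector of raw scores (may contain `NA`).
#' @param covariates data frame with `age_decade`, `sex`,
#'   `education_band` (any subset selectable via `terms`).
#' @param terms character vector of covariate columns to use.
#' @return A `cb_adjustment_model`: coefficients, R-squared, the terms and
#'   the factor levels seen.
#' @export
fit_confound_model <- function(values, covariates,
                               terms = c("age_decade", "sex",
                                         "education_band")) {
  keep <- !is.na(values)
  if (sum(keep) < 2 || length(unique(values[keep])) < 2) {
    cb_abort("need at least 2 distinct non-missing values",
             "cb_adjustment_error")
  }
  dat <- as.data.frame(lapply(covariates[keep, terms, drop = FALSE],
                              function(x) if (is.factor(x)) x else factor(x)))
  names(dat) <- terms
  for (tm in terms) {
    seen <- table(dat[[tm]])
    if (any(seen == 0)) {
      cb_abort(sprintf("covariate '%s' level '%s' has no observations", tm,
                       names(seen)[seen == 0][1]), "cb_adjustment_error")
    }
  }
  dat$.y <- values[keep]
  fit <- stats::lm(.y ~ ., data = dat)
  structure(list(
    terms = terms,
    coefficients = coef(fit),
    levels = lapply(dat[terms], levels),
    r_squared = summary(fit)$r.squared,
    sigma = summary(fit)$sigma,
    fit = fit), class = "cb_adjustment_model")
}

#' Residuals of a confound model on (possibly new) rows
#'
#' @param model a `cb_adjustment_model`.
#' @param covariates data frame holding the model's covariate columns.
#' @param values scores to residualize; missing in, missing out.
#' @return Numeric vector of residuals, `NA` where `values` is `NA`.
#' @export
residualize <- function(model, covariates, values) {
  out <- rep(NA_real_, length(values))
  keep <- !is.na(values)
  if (!any(keep)) return(out)
  newdat <- covariates[keep, model$terms, drop = FALSE]
  for (tm in model$terms) {
    lev <- model$levels[[tm]]
    vals <- as.character(newdat[[tm]])
    bad <- setdiff(unique(vals[!is.na(vals)]), lev)
    if (length(bad)) {
      cb_abort(sprintf("covariate '%s' has unseen level '%s'", tm, bad[1]),
               "cb_adjustment_error")
    }
    newdat[[tm]] <- factor(vals, levels = lev)
  }
  out[keep] <- values[keep] - predict(model$fit, newdata = newdat)
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps each value to the normal quantile of its offset-adjusted rank,
#' `qnorm((r - c) / (n - 2c + 1))`, with 1-based ranks, average ranks for
#' ties, and the Blom offset `c = 3/8` by default. Missing values are
#' preserved; the transform is strictly increasing across untied values
#' and invariant to any strictly increasing transformation of the input.
#'
#' @param values numeric vector.
#' @param offset rank offset constant `c` in `[0, 0.5]`.
#' @return Transformed vector with the same missingness pattern.
#' @export
#' @examples
#' rank_inverse_normal(c(10, 20, 30))   # middle value maps to 0
rank_inverse_normal <- function(values, offset = 3 / 8) {
  keep <- !is.na(values)
  n <- sum(keep)
  if (n < 2) {
    cb_abort("need at least 2 non-missing values to rank-transform",
             "cb_adjustment_error")
  }
  r <- rank(values[keep], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[keep] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Orient scores so that higher is always better
#'
#' @param values numeric vector.
#' @param direction `"higher_better"` (identity) or `"lower_better"`
#'   (negated).
#' @return Oriented vector.
#' @export
orient_scores <- function(values, direction) {
  if (length(direction) != 1 ||
      !direction %in% c("higher_better", "lower_better")) {
    cb_abort(paste0("unknown direction: ", paste(direction, collapse = "/")),
             "cb_adjustment_error")
  }
  if (direction == "lower_better") -values else values
}

#' Confound-adjust and normalize all task measures
#'
#' Per measure: fit the confound model on the configured fit population,
#' residualize all rows, rank-transform the residuals to normality, and
#' orient so high = good. The result is the participant-by-measure matrix
#' every downstream stage consumes.
#'
#' @param cohort a `cb_cohort`.
#' @param measures measure ids to adjust (default: all task measures
#'   present).
#' @param covariates confound-model terms.
#' @param fit_population `"pooled"` (default: the whole analysed sample)
#'   or `"controls"` (normative-style fit on controls only, residuals
#'   applied to everyone).
#' @param offset rank-INT offset constant.
#' @return A `cb_adjusted` object: `scores` (numeric matrix with
#'   missingness mask), `participants` (demographics tibble), `models`
#'   (per-measure `cb_adjustment_model`), `r_squared` table and the
#'   catalog.
#' @export
adjust_all <- function(cohort,
                       measures = NULL,
                       covariates = c("age_decade", "sex", "education_band"),
                       fit_population = c("pooled", "controls"),
                       offset = 3 / 8) {
  fit_population <- match.arg(fit_population)
  catalog <- attr(cohort, "catalog") %n% task_catalog()
  measures <- measures %n%
    intersect(all_measures(catalog), names(cohort))
  pre_oriented <- isTRUE(attr(cohort, "latency_oriented"))
  fit_rows <- if (fit_population == "controls") {
    cohort$group == "control"
  } else rep(TRUE, nrow(cohort))

  scores <- matrix(NA_real_, nrow(cohort), length(measures),
                   dimnames = list(as.character(cohort$participant_id),
                                   measures))
  models <- list()
  for (m in measures) {
    vals <- cohort[[m]]
    model <- tryCatch(
      fit_confound_model(ifelse(fit_rows, vals, NA), cohort,
                         terms = covariates),
      error = function(e) {
        cb_abort(paste0("measure ", m, ": ", conditionMessage(e)),
                 "cb_adjustment_error")
      })
    res <- residualize(model, cohort, vals)
    z <- rank_inverse_normal(res, offset = offset)
    dir <- measure_direction(catalog, m)
    if (pre_oriented) dir <- "higher_better"
    scores[, m] <- orient_scores(z, dir)
    models[[m]] <- model
  }
  structure(list(
    scores = scores,
    participants = cohort[, intersect(
      c("participant_id", "group", "age_years", "age_decade", "sex",
        "education_band", "device", "probable_rbd"), names(cohort))],
    models = models,
    r_squared = tibble::tibble(
      measure_id = measures,
      r_squared = vapply(models, function(m) m$r_squared, 0)),
    covariates = covariates,
    fit_population = fit_population,
    offset = offset,
    catalog = catalog), class = "cb_adjusted")
}

#' @export
print.cb_adjusted <- function(x, ...) {
  cat(sprintf(
    "<cb_adjusted> %d participants x %d measures (fit: %s; covariates: %s)\n",
    nrow(x$scores), ncol(x$scores), x$fit_population,
    paste(x$covariates, collapse = ", ")))
  invisible(x)
}

# Rebuild a cb_adjusted around a plain score matrix (internal helper used
# by composites and CV, which operate on derived columns).
adjusted_from_matrix <- function(scores, participants, catalog) {
  structure(list(scores = scores, participants = participants,
                 models = list(),
                 r_squared = tibble::tibble(measure_id = character(),
                                            r_squared = numeric()),
                 covariates = character(), fit_population = "pooled",
                 offset = 3 / 8, catalog = catalog),
            class = "cb_adjusted")
}
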