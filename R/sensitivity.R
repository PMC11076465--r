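#' Cross-validate the group model for a composite score
#'
#' Refits the group-contrast linear model on training folds and predicts
#' the held-out participants, assembling a full out-of-fold prediction
#' vector. Folds are stratified by group so every training set contains
#' all group levels; leave-one-out is the `folds = n` special case and is
#' available directly as `scheme = "loo"`.
#'
#' @param composite a `cb_composites`.
#' @param scheme `"loo"` or `"kfold"`.
#' @param folds number of folds for `"kfold"`.
#' @param seed fold-assignment seed (recorded in the result).
#' @param covariates optional data frame of extra predictors aligned with
#'   the composite rows (e.g. demographics); default group-only, matching
#'   the primary contrast model.
#' @param max_refolds times to redraw folds if a training fold loses a
#'   group level.
#' @return A `cb_cv_result`: `predictions` tibble (participant_id, group,
#'   observed, predicted, fold), `correlation`, `mse`, `fold_sizes`,
#'   `scheme`, `seed`.
#' @export
crossvalidate_composite_model <- function(composite,
                                          scheme = c("kfold", "loo"),
                                          folds = 25, seed = 1,
                                          covariates = NULL,
                                          max_refolds = 10) {
  scheme <- match.arg(scheme)
  n <- nrow(composite)
  if (scheme == "loo") folds <- n
  if (n < folds) {
    cb_abort(sprintf("n = %d below the number of folds (%d)", n, folds),
             "cb_cv_error")
  }
  dat <- data.frame(.y = composite$score,
                    group = droplevels(factor(composite$group)))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)

  assign_folds <- function(seed_i) {
    with_preserved_seed(seed_i, {
      fold <- integer(n)
      for (g in levels(dat$group)) {
        idx <- which(dat$group == g)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fold
    })
  }
  ok_folds <- function(fold) {
    all(vapply(seq_len(folds), function(k) {
      train <- dat$group[fold != k]
      all(levels(dat$group) %in% as.character(train))
    }, TRUE))
  }
  fold <- assign_folds(seed)
  tries <- 0
  while (!ok_folds(fold)) {
    tries <- tries + 1
    if (tries > max_refolds) {
      cb_abort("could not build folds with all groups in every training set",
               "cb_cv_error")
    }
    inform(sprintf("refolding (attempt %d): a training fold lost a group",
                   tries))
    fold <- assign_folds(seed + tries)
  }
  pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- stats::lm(.y ~ ., data = dat[!test, , drop = FALSE])
    pred[test] <- predict(fit, newdata = dat[test, , drop = FALSE])
  }
  obs <- dat$.y
  mse <- mean((pred - obs)^2)
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_ else
    stats::cor(pred, obs)
  structure(list(
    predictions = tibble::tibble(
      participant_id = composite$participant_id, group = composite$group,
      observed = obs, predicted = pred, fold = fold),
    correlation = r, mse = mse,
    fold_sizes = as.integer(table(factor(fold, levels = seq_len(folds)))),
    scheme = scheme, folds = folds, seed = seed), class = "cb_cv_result")
}

#' @export
print.cb_cv_result <- function(x, ...) {
  cat(sprintf("<cb_cv_result> %s (%d folds): r = %.3f, MSE = %.3f\n",
              x$scheme, x$folds, x$correlation, x$mse))
  invisible(x)
}

#' Group contrasts under alternative modelling strategies
#'
#' Re-estimates every per-measure group contrast under a model variant
#' and summarizes agreement with the primary two-step analysis
#' (residualize on demographics, rank-normalize, contrast groups):
#' \describe{
#'   \item{two_step}{the primary analysis itself.}
#'   \item{two_step_covariates}{adjusted scores contrasted with the
#'     sociodemographic variables entered again alongside group, guarding
#'     against residual confounding.}
#'   \item{one_model}{rank-normalized raw scores modelled with group and
#'     all sociodemographic variables in a single regression.}
#'   \item{continuous_age_cubic}{as `one_model` but age entered as a
#'     continuous orthogonal cubic polynomial instead of decade
#'     categories.}
#' }
#'
#' @param cohort a `cb_cohort`.
#' @param variant one of the variants above.
#' @param measures measure ids (default: all task measures).
#' @param reference reference group.
#' @return List: `contrasts` (tibble with variant label), `agreement`
#'   (vs the primary analysis: `max_abs_delta_smd`, `sign_agreement`).
#' @export
model_variant_contrasts <- function(cohort,
                                    variant = c("two_step",
                                                "two_step_covariates",
                                                "one_model",
                                                "continuous_age_cubic"),
                                    measures = NULL,
                                    reference = "control") {
  variant <- match.arg(variant)
  catalog <- attr(cohort, "catalog") %n% task_catalog()
  measures <- measures %n% intersect(all_measures(catalog), names(cohort))
  groups <- setdiff(levels(droplevels(cohort$group)), reference)

  primary <- variant_smds(cohort, "two_step", measures, reference, groups,
                          catalog)
  this <- if (variant == "two_step") primary else
    variant_smds(cohort, variant, measures, reference, groups, catalog)
  both <- dplyr::inner_join(primary, this,
                            by = c("measure_id", "contrast"),
                            suffix = c("_primary", "_variant"))
  agreement <- list(
    max_abs_delta_smd = max(abs(both$smd_variant - both$smd_primary)),
    sign_agreement = mean(sign(both$smd_variant) == sign(both$smd_primary)))
  this$variant <- variant
  list(contrasts = this, agreement = agreement)
}

variant_smds <- function(cohort, variant, measures, reference, groups,
                         catalog) {
  pre_oriented <- isTRUE(attr(cohort, "latency_oriented"))
  if (variant %in% c("two_step", "two_step_covariates")) {
    adjusted <- adjust_all(cohort, measures = measures)
    rows <- lapply(measures, function(m) {
      y <- adjusted$scores[, m]
      keep <- !is.na(y)
      dat <- data.frame(.y = y[keep],
                        group = factor(cohort$group[keep],
                                       levels = c(reference, groups)))
      if (variant == "two_step_covariates") {
        dat <- cbind(dat, cohort[keep, c("age_decade", "sex",
                                         "education_band")])
      }
      fit <- stats::lm(.y ~ ., data = dat)
      tibble::tibble(measure_id = m,
                     contrast = paste0(groups, "-", reference),
                     smd = unname(coef(fit)[paste0("group", groups)]))
    })
    return(dplyr::bind_rows(rows))
  }
  rows <- lapply(measures, function(m) {
    vals <- cohort[[m]]
    dir <- measure_direction(catalog, m)
    if (pre_oriented) dir <- "higher_better"
    z <- orient_scores(rank_inverse_normal(vals), dir)
    keep <- !is.na(z)
    dat <- data.frame(.y = z[keep],
                      group = factor(cohort$group[keep],
                                     levels = c(reference, groups)),
                      sex = cohort$sex[keep],
                      education_band = cohort$education_band[keep])
    if (variant == "one_model") {
      dat$age_decade <- cohort$age_decade[keep]
      fit <- stats::lm(.y ~ ., data = dat)
    } else {
      age <- cohort$age_years[keep]
      fit <- stats::lm(.y ~ group + poly(age, 3) + sex + education_band,
                       data = dat)
    }
    tibble::tibble(measure_id = m,
                   contrast = paste0(groups, "-", reference),
                   smd = unname(coef(fit)[paste0("group", groups)]))
  })
  dplyr::bind_rows(rows)
}

#' Composite contrasts for RBD-defined subgroups
#'
#' Splits PD by probable RBD (RBDSQ strictly greater than 6) and
#' contrasts the accuracy and latency composites for: PD with vs without
#' probable RBD, PD with probable RBD vs idiopathic RBD, and each of the
#' three patient subgroups vs controls. Empty subgroups skip their
#' comparisons with a warning.
#'
#' @param cohort a `cb_cohort` (provides group and `probable_rbd`).
#' @param composites named list of `cb_composites`, e.g.
#'   `list(accuracy = ..., latency = ...)`.
#' @return Tibble: comparison, composite, smd, p_value, n_a, n_b.
#' @export
subgroup_contrasts <- function(cohort, composites) {
  grp <- as.character(cohort$group)
  prob <- cohort$probable_rbd
  sub <- rep(NA_character_, nrow(cohort))
  sub[grp == "control"] <- "control"
  sub[grp == "RBD"] <- "iRBD"
  sub[grp == "PD" & prob] <- "PD+RBD"
  sub[grp == "PD" & !prob] <- "PD-RBD"
  pairs <- list(c("PD+RBD", "PD-RBD"), c("PD+RBD", "iRBD"),
                c("PD+RBD", "control"), c("PD-RBD", "control"),
                c("iRBD", "control"))
  out <- list()
  for (pair in pairs) {
    for (lab in names(composites)) {
      comp <- composites[[lab]]
      s <- sub[match(comp$participant_id, cohort$participant_id)]
      a <- comp$score[s == pair[1] & !is.na(s)]
      b <- comp$score[s == pair[2] & !is.na(s)]
      if (length(a) < 2 || length(b) < 2) {
        warn(sprintf("comparison %s vs %s skipped for %s composite (n = %d, %d)",
                     pair[1], pair[2], lab, length(a), length(b)))
        next
      }
      fit <- stats::t.test(a, b, var.equal = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        comparison = paste0(pair[1], " vs ", pair[2]), composite = lab,
        smd = mean(a) - mean(b), p_value = fit$p.value,
        n_a = length(a), n_b = length(b))
    }
  }
  dplyr::bind_rows(out)
}

#' Correlations between cognitive composites and motor severity
#'
#' Pearson correlations, within the PD group, between each supplied
#' composite and (a) the UPDRS-III total and (b) a focused composite of
#' the finger-tapping / hand-movement sub-items (the standardized mean of
#' the item z-scores).
#'
#' @param cohort a `cb_cohort` with `updrs3` and `updrs3_ft_hand*`
#'   columns.
#' @param composites named list of `cb_composites`.
#' @param group group whose motor scores are analysed.
#' @return Tibble: composite, motor_measure, r, p_value, n.
#' @export
motor_confound_correlation <- function(cohort, composites, group = "PD") {
  rows <- cohort$group == group
  items <- grep("^updrs3_ft_hand", names(cohort), value = TRUE)
  itemz <- scale(as.matrix(cohort[rows, items]))
  ft <- rowMeans(itemz)
  ft <- (ft - mean(ft, na.rm = TRUE)) / stats::sd(ft, na.rm = TRUE)
  motor <- list(updrs3 = cohort$updrs3[rows], fingertap_hand = ft)
  ids <- cohort$participant_id[rows]
  out <- list()
  for (lab in names(composites)) {
    comp <- composites[[lab]]
    sc <- comp$score[match(ids, comp$participant_id)]
    for (mm in names(motor)) {
      keep <- !is.na(sc) & !is.na(motor[[mm]])
      if (sum(keep) < 3) {
        cb_abort(sprintf("fewer than 3 pairs for %s vs %s", lab, mm),
                 "cb_sensitivity_error")
      }
      ct <- stats::cor.test(sc[keep], motor[[mm]][keep])
      out[[length(out) + 1]] <- tibble::tibble(
        composite = lab, motor_measure = mm, r = unname(ct$estimate),
        p_value = ct$p.value, n = sum(keep))
    }
  }
  dplyr::bind_rows(out)
}
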