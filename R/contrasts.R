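#' Group contrasts on adjusted scores
#'
#' Per-measure ordinary least squares of the adjusted score on group
#' dummies. Because adjusted scores are unit-variance normal scores, the
#' group coefficients are standardized mean differences (SMD) in SD units;
#' the sign convention is negative = worse than the reference group.
#'
#' @param adjusted a `cb_adjusted`.
#' @param measure_id measure to contrast (column of `adjusted$scores`).
#' @param groups groups to compare against the reference (default: all
#'   non-reference groups present).
#' @param reference reference group label.
#' @return Tibble of class `cb_contrast`: measure_id, contrast, smd, se,
#'   p_value, n_reference, n_group.
#' @export
group_contrast <- function(adjusted, measure_id, groups = NULL,
                           reference = "control") {
  grp <- as.character(adjusted$participants$group)
  present <- unique(grp)
  groups <- groups %n% setdiff(intersect(GROUP_LEVELS, present), reference)
  absent <- setdiff(c(reference, groups), present)
  if (length(absent)) {
    cb_abort(paste0("group(s) not present: ", paste(absent, collapse = ", ")),
             "cb_contrast_error")
  }
  y <- adjusted$scores[, measure_id]
  keep <- !is.na(y) & grp %in% c(reference, groups)
  g <- factor(grp[keep], levels = c(reference, groups))
  fit <- stats::lm(y[keep] ~ g)
  sm <- summary(fit)$coefficients
  rows <- paste0("g", groups)
  # Degenerate case: all values identical leaves nothing to test.
  out <- tibble::tibble(
    measure_id = measure_id,
    contrast = paste0(groups, "-", reference),
    smd = unname(coef(fit)[rows]),
    se = ifelse(rows %in% rownames(sm), sm[rows, "Std. Error"], NA_real_),
    p_value = ifelse(rows %in% rownames(sm), sm[rows, "Pr(>|t|)"],
                     NA_real_),
    n_reference = sum(g == reference),
    n_group = vapply(groups, function(x) sum(g == x), 0L))
  if (all(!is.na(y[keep])) && stats::var(y[keep]) == 0) {
    out$smd <- 0
    out$p_value <- 1
  }
  class(out) <- c("cb_contrast", class(out))
  out
}

#' Two-way ANOVA of adjusted scores by group and task
#'
#' Fits `value ~ group * task` on long stacked scores and partitions the
#' sums of squares with Type-II tests (robust to the unbalanced group
#' sizes; Type III available). Tukey HSD post-hoc comparisons are run on
#' the group marginal means to identify which group differences drive a
#' significant group term.
#'
#' @param long_scores data frame with columns `participant_id`, `group`,
#'   `task`, `value` (one row per participant x task, missing rows
#'   omitted).
#' @param ss_type `"II"` or `"III"`.
#' @return A `cb_anova`: `table` (term, sum_sq, df, statistic, p_value),
#'   `tukey` (tibble of pairwise group differences with adjusted p), and
#'   `zero_variance` flag.
#' @export
two_way_anova <- function(long_scores, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  need <- c("group", "task", "value")
  if (!all(need %in% names(long_scores))) {
    cb_abort("long_scores needs columns group, task, value",
             "cb_contrast_error")
  }
  d <- long_scores[!is.na(long_scores$value), , drop = FALSE]
  d$group <- droplevels(factor(d$group))
  d$task <- droplevels(factor(d$task))
  if (nlevels(d$group) < 2 || nlevels(d$task) < 2) {
    cb_abort("need at least 2 groups and 2 tasks", "cb_contrast_error")
  }
  cells <- table(d$group, d$task)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(i) {
      paste0(rownames(cells)[i[1]], ":", colnames(cells)[i[2]])
    })
    cb_abort(paste0("empty group x task cell(s): ",
                    paste(lab, collapse = ", ")), "cb_contrast_error")
  }
  zero_var <- stats::var(d$value) == 0
  if (zero_var) {
    tab <- tibble::tibble(
      term = c("group", "task", "group:task"),
      sum_sq = 0, df = NA_real_, statistic = 0, p_value = 1)
    tukey <- tibble::tibble(comparison = character(), difference = numeric(),
                            lower = numeric(), upper = numeric(),
                            p_adjusted = numeric())
    return(structure(list(table = tab, tukey = tukey, zero_variance = TRUE,
                          ss_type = ss_type), class = "cb_anova"))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(value ~ group * task, data = d)
  ctab <- car::Anova(fit, type = ss_type)
  terms <- c("group", "task", "group:task")
  tab <- tibble::tibble(
    term = terms,
    sum_sq = ctab[terms, "Sum Sq"],
    df = ctab[terms, "Df"],
    statistic = ctab[terms, "F value"],
    p_value = ctab[terms, "Pr(>F)"])
  tk <- stats::TukeyHSD(stats::aov(value ~ group + task, data = d),
                        which = "group")$group
  tukey <- tibble::tibble(
    comparison = rownames(tk),
    difference = tk[, "diff"],
    lower = tk[, "lwr"],
    upper = tk[, "upr"],
    p_adjusted = tk[, "p adj"])
  structure(list(table = tab, tukey = tukey, zero_variance = FALSE,
                 ss_type = ss_type), class = "cb_anova")
}

#' Stack an adjusted matrix to long (participant, group, task, value)
#'
#' @param adjusted a `cb_adjusted`.
#' @param measures columns to stack (default all).
#' @return Long tibble suitable for [two_way_anova()].
#' @export
stack_adjusted <- function(adjusted, measures = NULL) {
  measures <- measures %n% colnames(adjusted$scores)
  part <- adjusted$participants
  out <- tidyr::expand_grid(i = seq_len(nrow(part)), task = measures)
  tibble::tibble(
    participant_id = part$participant_id[out$i],
    group = part$group[out$i],
    task = out$task,
    value = adjusted$scores[cbind(out$i, match(out$task,
                                               colnames(adjusted$scores)))])
}

#' Age-decade contrasts in a normative sample
#'
#' Contrasts each older decade against the 50s with age decade as a
#' categorical factor, allowing non-linear age effects. The scores passed
#' in should be adjusted for sex and education only, since age is the
#' predictor of interest here.
#'
#' @param adjusted a `cb_adjusted` built from a normative sample with
#'   `covariates = c("sex", "education_band")`.
#' @param measure_id measure to contrast.
#' @param reference reference decade.
#' @return A `cb_contrast` tibble with one row per non-reference decade.
#' @export
age_decade_contrast <- function(adjusted, measure_id, reference = "50s") {
  dec <- as.character(adjusted$participants$age_decade)
  missing_dec <- setdiff(DECADE_LEVELS, unique(dec))
  if (length(missing_dec)) {
    cb_abort(paste0("decade(s) not present: ",
                    paste(missing_dec, collapse = ", ")),
             "cb_contrast_error")
  }
  y <- adjusted$scores[, measure_id]
  keep <- !is.na(y)
  g <- factor(dec[keep], levels = c(reference,
                                    setdiff(DECADE_LEVELS, reference)))
  fit <- stats::lm(y[keep] ~ g)
  sm <- summary(fit)$coefficients
  lev <- setdiff(DECADE_LEVELS, reference)
  rows <- paste0("g", lev)
  out <- tibble::tibble(
    measure_id = measure_id,
    contrast = paste0(lev, "-", reference),
    smd = unname(coef(fit)[rows]),
    se = sm[rows, "Std. Error"],
    p_value = sm[rows, "Pr(>|t|)"],
    n_reference = sum(g == reference),
    n_group = vapply(lev, function(x) sum(g == x), 0L))
  class(out) <- c("cb_contrast", class(out))
  out
}

#' Classify a standardized effect size
#'
#' Bins the absolute SMD using Sawilowsky's extension of Cohen's
#' thresholds: 0.1 very small, 0.2 small, 0.5 medium, 0.8 large, 1.2 very
#' large, 2.0 huge; below 0.1 is negligible. Thresholds are inclusive
#' upward (an SMD of exactly 0.5 is "medium").
#'
#' @param smd standardized mean difference(s); finite.
#' @return Character vector of labels.
#' @export
#' @examples
#' effect_size_label(c(0, 0.65, 1.2))
effect_size_label <- function(smd) {
  if (any(!is.finite(smd))) {
    cb_abort("SMD must be finite", "cb_contrast_error")
  }
  bins <- c(0.1, 0.2, 0.5, 0.8, 1.2, 2.0)
  labels <- c("negligible", "very small", "small", "medium", "large",
              "very large", "huge")
  labels[findInterval(abs(smd), bins) + 1]
}
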