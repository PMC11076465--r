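#' Generate a synthetic clinical cohort with known ground truth
#'
#' Draws participants for the three clinical groups (control, PD, RBD)
#' from the latent factor model in the configuration: per participant a
#' 5-vector of correlated cognitive factors is drawn, shifted by group,
#' age-decade, education and PD-subgroup effects; each measure is the
#' loading-weighted factor score plus task-specific group offsets, sex and
#' device effects and unique noise. Supervised scale scores (MoCA at two
#' timepoints with section subscores, MMSE, UPDRS I-IV with finger-tapping
#' / hand-movement items, RBDSQ, Purdue) derive from the same latents, the
#' screening scales with integer steps and a hard ceiling at 30.
#' Missingness is applied measure-wise at the configured rates.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return List with `cohort` (a `cb_cohort`) and `truth` (a `cb_truth`
#'   list recording all realized parameters, the per-participant latent
#'   factor scores and the seed).
#' @export
generate_cohort <- function(config, seed) {
  if (any(config$n_per_group < 2)) {
    cb_abort("need at least 2 participants per group", "cb_generator_error")
  }
  out <- with_preserved_seed(seed, {
    n <- sum(config$n_per_group)
    group <- factor(rep(GROUP_LEVELS, config$n_per_group[GROUP_LEVELS]),
                    levels = GROUP_LEVELS)
    demo <- draw_demographics(config, group)
    demo$device <- factor(
      sample(DEVICE_LEVELS, n, TRUE, config$device_props_cohort),
      levels = DEVICE_LEVELS)
    build_cohort(config, demo, group_effects = TRUE, scales = TRUE)
  })
  out$truth$seed <- seed
  out
}

#' Generate a device-diverse normative sample
#'
#' All participants are controls, balanced across the four age decades
#' (50s-80s) with the configured device mix; age-decade factor effects
#' apply, including the positive word-knowledge trend with age.
#'
#' @inheritParams generate_cohort
#' @return A `cb_cohort`; the ground truth is attached as attribute
#'   `"truth"`.
#' @export
generate_normative_sample <- function(config, seed) {
  if (config$n_per_decade < 2) {
    cb_abort("need at least 2 participants per decade", "cb_generator_error")
  }
  with_preserved_seed(seed, {
    n <- 4L * as.integer(config$n_per_decade)
    group <- factor(rep("control", n), levels = GROUP_LEVELS)
    decade <- factor(rep(DECADE_LEVELS, each = config$n_per_decade),
                     levels = DECADE_LEVELS)
    age <- 10 * (4 + as.integer(decade)) + floor(runif(n, 0, 10))
    demo <- tibble::tibble(
      participant_id = sprintf("N%05d", seq_len(n)),
      group = group,
      age_years = age,
      age_decade = decade,
      sex = factor(sample(SEX_LEVELS, n, TRUE, c(0.5, 0.5)),
                   levels = SEX_LEVELS),
      education_band = factor(
        sample(EDUCATION_LEVELS, n, TRUE, config$education_probs),
        levels = EDUCATION_LEVELS),
      device = factor(
        sample(DEVICE_LEVELS, n, TRUE, config$device_props_normative),
        levels = DEVICE_LEVELS))
    out <- build_cohort(config, demo, group_effects = FALSE, scales = FALSE)
    out$truth$seed <- seed
    cohort <- out$cohort
    attr(cohort, "truth") <- out$truth
    cohort
  })
}

draw_demographics <- function(config, group) {
  n <- length(group)
  g <- as.character(group)
  age <- pmin(pmax(round(rnorm(n, config$age_means[g], config$age_sd)),
                   50), 89)
  sex <- ifelse(runif(n) < config$female_frac[g], "female", "male")
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    group = group,
    age_years = age,
    age_decade = factor(paste0(floor(age / 10) * 10, "s"),
                        levels = DECADE_LEVELS),
    sex = factor(sex, levels = SEX_LEVELS),
    education_band = factor(
      sample(EDUCATION_LEVELS, n, TRUE, config$education_probs),
      levels = EDUCATION_LEVELS))
}

# Core sampling shared by the cohort and normative generators. Assumes the
# RNG is already seeded.
build_cohort <- function(config, demo, group_effects, scales) {
  catalog <- config$catalog
  L <- config$loadings
  n <- nrow(demo)
  g <- as.character(demo$group)
  measures <- rownames(L)

  cal <- if (group_effects) calibrate_group_effects(config) else NULL

  # probable-RBD status (RBDSQ > 6) and within-PD subgroup deviations
  sub <- config$rbd_subgroup
  p_prob <- c(control = sub$probable_control,
              PD = sub$pd_probable_fraction, RBD = sub$probable_rbd)
  probable <- runif(n) < p_prob[g]

  # latent factors: correlated base + factor-level shifts
  ch <- tryCatch(chol(config$phi), error = function(e) {
    cb_abort("factor correlation matrix is not positive definite",
             "cb_generator_error")
  })
  f <- matrix(rnorm(n * 5), n, 5) %*% ch
  colnames(f) <- FACTOR_LABELS
  dec_idx <- as.integer(demo$age_decade) - 1L
  f <- f + outer(dec_idx, config$age_gradients)
  f[, 1:4] <- f[, 1:4] + config$education_offsets[demo$education_band]
  if (group_effects) {
    for (grp in colnames(cal$factor_shift)) {
      rows <- g == grp
      f[rows, ] <- f[rows, ] +
        matrix(cal$factor_shift[, grp], sum(rows), 5, byrow = TRUE)
    }
    # PD subgroup with probable RBD: worse response times and a milder
    # accuracy trend, centered so the PD marginal deficit is unchanged.
    pd <- g == "PD"
    dev_rt <- ifelse(probable, -(1 - sub$pd_probable_fraction),
                     sub$pd_probable_fraction)
    f[pd, "motor_rt"] <- f[pd, "motor_rt"] + sub$latency_gap * dev_rt[pd]
    f[pd, 1:4] <- f[pd, 1:4] + sub$accuracy_gap * dev_rt[pd]
  }

  X <- f %*% t(L) +
    matrix(rnorm(n * length(measures)), n) %*% diag(sqrt(config$psi))
  colnames(X) <- measures
  if (group_effects) {
    for (grp in colnames(cal$measure_extra)) {
      rows <- g == grp
      X[rows, ] <- X[rows, ] +
        matrix(cal$measure_extra[, grp], sum(rows), length(measures),
               byrow = TRUE)
    }
  }
  if (!is.null(config$age_measure_offsets)) {
    X <- X + t(config$age_measure_offsets[, dec_idx + 1L, drop = FALSE])
  }
  X <- X + outer(as.numeric(demo$sex == "female"), config$sex_effects)
  X <- X + t(config$device_offsets[, as.character(demo$device)])

  cohort <- demo
  latency_oriented <- TRUE
  lat <- catalog_measures(catalog, "latency")
  if (config$emit_raw_latency) {
    X[, lat] <- round(exp(6.2 - 0.25 * X[, lat]))
    latency_oriented <- FALSE
  }
  for (m in measures) cohort[[m]] <- X[, m]

  if (scales) {
    cohort <- cbind_scales(cohort, config, f, g, probable)
  }

  rates <- config$missingness[intersect(names(config$missingness),
                                        names(cohort))]
  if (length(rates) && any(rates > 0)) {
    cohort <- apply_missingness(cohort, rates,
                                seed = sample.int(2^31 - 1, 1))
  }

  cohort <- as_cohort(cohort, catalog)
  attr(cohort, "latency_oriented") <- latency_oriented
  truth <- structure(list(
    seed = NA_integer_, config = config, calibration = cal,
    factor_scores = f, probable_rbd = probable,
    device = demo$device), class = "cb_truth")
  list(cohort = cohort, truth = truth)
}

# Supervised scales derived from the shifted latents. h is the
# standardized accuracy latent; the MoCA total is a sum of seven integer
# section scores each clipped at its maximum, which yields the ceiling
# compression that blunts its group discriminability.
cbind_scales <- function(cohort, config, f, g, probable) {
  n <- nrow(cohort)
  sp <- config$scale_params
  mp <- config$motor_params
  h_raw <- rowMeans(f[, 1:4])
  h <- h_raw / sqrt(mean(config$phi[1:4, 1:4]))
  # stable scale-specific trait shared across timepoints, so retest
  # reliability exceeds the scale's correlation with cognition alone
  u <- rnorm(n)

  section <- function(h) {
    vapply(seq_along(sp$moca_section_max), function(j) {
      raw <- sp$moca_section_base[j] + sp$moca_section_weight[j] * h +
        sp$moca_section_stable[j] * u +
        rnorm(n, 0, sp$moca_section_noise[j])
      pmin(pmax(round(raw), 0), sp$moca_section_max[j])
    }, numeric(n))
  }
  subs <- section(h)
  colnames(subs) <- paste0("moca_sub", seq_len(ncol(subs)))
  cohort <- cbind(cohort, subs)
  cohort$moca_total.assessment <- rowSums(subs)
  cohort$moca_total.baseline <- rowSums(section(h))
  cohort$mmse_total.baseline <- pmin(pmax(round(
    sp$mmse_base + sp$mmse_weight * h + rnorm(n, 0, sp$mmse_noise)), 0), 30)

  rt <- f[, "motor_rt"]
  base <- do.call(rbind, mp$updrs_base[g])
  cohort$updrs1 <- pmax(round(base[, 1] + rnorm(n, 0, 2.5)), 0)
  cohort$updrs2 <- pmax(round(base[, 2] + rnorm(n, 0, 3)), 0)
  cohort$updrs3 <- pmax(round(base[, 3] - mp$updrs3_rt_coupling * rt +
                                rnorm(n, 0, mp$updrs3_noise)), 0)
  cohort$updrs4 <- pmax(round(base[, 4] + rnorm(n, 0, 1.5)), 0)
  for (j in 1:4) {
    cohort[[paste0("updrs3_ft_hand", j)]] <- pmin(pmax(round(
      mp$item_base[g] - mp$item_rt_coupling * rt +
        rnorm(n, 0, mp$item_noise)), 0), 4)
  }
  cohort$purdue <- mp$purdue_base[g] + 2 * rt + rnorm(n, 0, 5)

  low <- rnorm(n, config$rbdsq_low_mean[g], 1.6)
  high <- rnorm(n, config$rbdsq_probable_mean, 1.6)
  rbdsq <- round(ifelse(probable, pmax(high, 7), pmin(low, 6)))
  cohort$rbdsq <- pmin(pmax(rbdsq, 0), 13)
  cohort
}

#' Apply measure-wise missingness
#'
#' Sets task score cells missing independently with the given
#' probabilities; demographic and scale columns are never touched.
#'
#' @param cohort a `cb_cohort` (or plain data frame with task columns).
#' @param rates named vector of missingness probabilities per measure
#'   column, or a single rate recycled over all task measures.
#' @param seed integer seed.
#' @return The cohort with cells set to `NA`.
#' @export
apply_missingness <- function(cohort, rates, seed) {
  if (any(rates < 0 | rates > 1)) {
    cb_abort("missingness rates must be in [0, 1]", "cb_generator_error")
  }
  catalog <- attr(cohort, "catalog") %n% task_catalog()
  if (is.null(names(rates))) {
    if (length(rates) != 1) {
      cb_abort("unnamed rates must have length 1", "cb_generator_error")
    }
    rates <- stats::setNames(
      rep(rates, length(all_measures(catalog))), all_measures(catalog))
  }
  with_preserved_seed(seed, {
    for (m in intersect(names(rates), names(cohort))) {
      if (rates[[m]] > 0) {
        drop <- runif(nrow(cohort)) < rates[[m]]
        cohort[[m]][drop] <- NA_real_
      }
    }
    cohort
  })
}

# Evaluate code under a fixed RNG state, restoring the caller's state.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
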