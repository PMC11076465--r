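#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the data model the analysis pipeline assumes:
#' 35 task measures (19 primary scores, 16 secondary latencies) produced by
#' 5 correlated latent cognitive factors (executive, visuospatial/attention,
#' short-term memory, word knowledge, motor reaction time), with group
#' deficits, non-linear age-decade effects, sex and education effects,
#' additive device offsets, supervised scale scores (MoCA, MMSE, UPDRS,
#' RBDSQ) derived from the same latents, and task-level missingness. All
#' measures are emitted as unit-variance normal scores oriented high = good
#' (a raw-millisecond emission mode for latencies is available via
#' `emit_raw_latency`).
#'
#' Group deficits are specified on the scale the analysis reports: the
#' pooled-standardized one-factor global composite, in SD units. A
#' closed-form calibration (see [calibrate_group_effects()]) maps those
#' targets to latent factor-mean shifts plus per-measure offsets whose
#' relative pattern follows `accuracy_profile` / `latency_profile`.
#'
#' @param n_per_group named integer vector, participants per clinical group.
#' @param n_per_decade normative-sample size per age decade (50s-80s).
#' @param group_accuracy named deficits (SD units, positive = worse than
#'   control) on the global accuracy composite.
#' @param group_latency deficits on the global latency composite.
#' @param inter_factor_cor correlation between accuracy factors (positive
#'   manifold); the motor-RT factor uses half this value.
#' @param ... overrides for the remaining defaults (see
#'   `generator_config()$...` names).
#' @return A list of class `cb_generator_config`.
#' @export
generator_config <- function(n_per_group = c(control = 50, PD = 59, RBD = 54),
                             n_per_decade = 1250,
                             group_accuracy = c(PD = 0.65, RBD = 0.45),
                             group_latency = c(PD = 0.61, RBD = 0.15),
                             inter_factor_cor = 0.20,
                             ...) {
  catalog <- task_catalog()
  load <- default_loadings(catalog)
  K <- ncol(load)
  phi <- matrix(inter_factor_cor, K, K,
                dimnames = list(FACTOR_LABELS, FACTOR_LABELS))
  phi[K, ] <- phi[, K] <- inter_factor_cor / 2
  diag(phi) <- 1
  implied <- diag(load %*% phi %*% t(load))
  if (any(implied >= 1)) {
    cb_abort("loading rows imply communality >= 1", "cb_generator_error")
  }
  cfg <- list(
    catalog = catalog,
    n_per_group = n_per_group,
    n_per_decade = n_per_decade,
    loadings = load,
    phi = phi,
    psi = 1 - implied,
    group_accuracy = group_accuracy,
    group_latency = group_latency,
    accuracy_profile = default_accuracy_profile(),
    latency_profile = default_latency_profile(catalog),
    rbd_subgroup = list(pd_probable_fraction = 0.25, probable_rbd = 0.92,
                        probable_control = 0.03, latency_gap = 0.35,
                        accuracy_gap = 0.10),
    age_gradients = c(executive = -0.22, visuospatial_attention = -0.18,
                      short_term_memory = -0.28, word_knowledge = 0.15,
                      motor_rt = -0.30),
    age_measure_offsets = NULL,
    sex_effects = default_sex_effects(catalog),
    education_offsets = c(`none` = 0, `<5y` = 0.12, `5-10y` = 0.25,
                          `>10y` = 0.40),
    device_offsets = default_device_offsets(catalog),
    device_props_cohort = c(computer = 0.80, tablet = 0.15, phone = 0.05),
    device_props_normative = c(computer = 0.50, tablet = 0.20, phone = 0.30),
    age_means = c(control = 72.8, PD = 66.0, RBD = 68.7),
    age_sd = 8.6,
    female_frac = c(control = 0.42, PD = 0.48, RBD = 0.11),
    education_probs = c(0.10, 0.25, 0.35, 0.30),
    scale_params = list(
      moca_section_max = c(5, 3, 6, 3, 2, 5, 6),
      moca_section_base = c(4.35, 2.90, 5.50, 2.75, 1.80, 3.80, 5.95),
      moca_section_weight = c(0.20, 0.08, 0.22, 0.11, 0.09, 0.30, 0.06),
      moca_section_stable = c(0.15, 0.06, 0.16, 0.08, 0.06, 0.22, 0.05),
      moca_section_noise = c(0.60, 0.35, 0.70, 0.45, 0.40, 0.90, 0.30),
      mmse_base = 28.6, mmse_weight = 0.45, mmse_noise = 0.9),
    motor_params = list(
      updrs_base = list(control = c(4.9, 0.9, 1.4, 0),
                        PD = c(9.8, 11.6, 30.7, 4.1),
                        RBD = c(7.2, 2.7, 6.8, 0)),
      updrs3_rt_coupling = 4.2, updrs3_noise = 9,
      item_base = c(control = 0.2, PD = 1.8, RBD = 0.5),
      item_rt_coupling = 0.8, item_noise = 0.7,
      purdue_base = c(control = 32.0, PD = 29.6, RBD = 32.3)),
    rbdsq_low_mean = c(control = 2.3, PD = 4.6, RBD = 5.8),
    rbdsq_probable_mean = 9.5,
    missingness = stats::setNames(rep(0.004, 35), all_measures(catalog)),
    emit_raw_latency = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    cb_abort(paste0("unknown generator option(s): ",
                    paste(unknown, collapse = ", ")), "cb_config_error")
  }
  cfg[names(dots)] <- dots
  if (any(cfg$n_per_group < 2)) {
    cb_abort("need at least 2 participants per group", "cb_generator_error")
  }
  # positive-definiteness of the implied measure covariance
  sig <- cfg$loadings %*% cfg$phi %*% t(cfg$loadings)
  diag(sig) <- diag(sig) + cfg$psi
  ok <- tryCatch({ chol(sig); TRUE }, error = function(e) FALSE)
  if (!ok) {
    cb_abort("implied measure covariance is not positive definite",
             "cb_generator_error")
  }
  class(cfg) <- "cb_generator_config"
  cfg
}

all_measures <- function(catalog) catalog_measures(catalog, "all")

# 35 x 5 loading matrix: primary scores follow a simple structure with at
# most two salient loadings per row; each secondary latency loads on the
# motor-RT factor plus a small loading on its task's dominant factor
# (harder trials are answered more slowly).
default_loadings <- function(catalog) {
  p <- function(t) paste0(t, ".primary")
  L <- matrix(0, 35, 5,
              dimnames = list(all_measures(catalog), FACTOR_LABELS))
  L[p("switching_stroop"), ] <- c(0.74, 0, 0, 0, 0)
  L[p("tower_of_london"), ] <- c(0.70, 0.22, 0, 0, 0)
  L[p("verbal_analogies"), ] <- c(0.18, 0, 0, 0.76, 0)
  L[p("word_definitions"), ] <- c(0, 0, 0, 0.85, 0)
  L[p("target_detection"), ] <- c(0.28, 0.62, 0, 0, 0)
  L[p("manipulations_2d"), ] <- c(0, 0.70, 0, 0, 0)
  L[p("four_towers"), ] <- c(0, 0.68, 0, 0, 0)
  L[p("picture_completion"), ] <- c(0, 0.62, 0, 0, 0)
  L[p("blocks"), ] <- c(0.25, 0.62, 0, 0, 0)
  L[p("emotional_discrimination"), ] <- c(0, 0.58, 0, 0, 0)
  L[p("digit_span"), ] <- c(0, 0, 0.70, 0, 0)
  L[p("spatial_span"), ] <- c(0, 0.28, 0.60, 0, 0)
  L[p("recognition_immediate"), ] <- c(0, 0, 0.72, 0, 0)
  L[p("recognition_delayed"), ] <- c(0, 0, 0.74, 0, 0)
  L[p("card_pairs"), ] <- c(0, 0, 0.62, 0, 0)
  L[p("pal"), ] <- c(0.38, 0, 0.36, 0, 0)
  L[p("srt"), ] <- c(0, 0, 0, 0, 0.80)
  L[p("motor_control"), ] <- c(0, 0, 0, 0, 0.74)
  L[p("trail_making"), ] <- c(0.26, 0, 0, 0, 0.66)
  for (t in catalog$task_id[catalog$has_secondary]) {
    row <- paste0(t, ".secondary")
    dom <- which.max(abs(L[p(t), 1:4]))
    L[row, 5] <- 0.68
    L[row, dom] <- 0.18
  }
  L
}

# Relative per-measure deficit pattern for the accuracy composite,
# qualitatively matching the published task-level ordering: memory,
# language and executive/attention tasks carry the deficit; planning and
# card-matching tasks barely differ from controls. Mean-normalized during
# calibration, so only ratios matter.
default_accuracy_profile <- function() {
  c(recognition_immediate.primary = 1.40, recognition_delayed.primary = 1.50,
    word_definitions.primary = 1.55, verbal_analogies.primary = 1.40,
    switching_stroop.primary = 1.30, target_detection.primary = 1.25,
    blocks.primary = 1.05, emotional_discrimination.primary = 1.00,
    pal.primary = 0.95, picture_completion.primary = 0.95,
    digit_span.primary = 0.65, spatial_span.primary = 0.50,
    manipulations_2d.primary = 0.55, four_towers.primary = 0.60,
    tower_of_london.primary = 0.45, card_pairs.primary = 0.40)
}

default_latency_profile <- function(catalog) {
  m <- catalog_measures(catalog, "latency")
  prof <- stats::setNames(rep(1, length(m)), m)
  prof[c("srt.primary", "motor_control.primary", "trail_making.primary")] <- 1.25
  prof
}

default_sex_effects <- function(catalog) {
  eff <- stats::setNames(rep(0, 35), all_measures(catalog))
  eff["emotional_discrimination.primary"] <- 0.12   # female advantage
  eff["word_definitions.primary"] <- 0.05
  eff[catalog_measures(catalog, "latency")] <- -0.04
  eff
}

# Additive device offsets (SD units, computer = reference). The three
# speeded tasks are strongly device dependent; secondary latencies mildly
# so; accuracy scores of recommended tasks nearly device-free.
default_device_offsets <- function(catalog) {
  m <- all_measures(catalog)
  off <- matrix(0, length(m), 3, dimnames = list(m, DEVICE_LEVELS))
  phone <- stats::setNames(rep(-0.04, length(m)), m)
  phone[catalog_measures(catalog, "secondary")] <- -0.12
  phone["srt.primary"] <- -0.35
  phone["motor_control.primary"] <- -0.30
  phone["picture_completion.primary"] <- -0.25
  phone["trail_making.primary"] <- -0.10
  final <- paste0(catalog$task_id[catalog$final_battery_member &
                                    catalog$primary_kind == "accuracy"],
                  ".primary")
  phone[final] <- -0.05
  off[, "phone"] <- phone
  off[, "tablet"] <- phone / 2
  off
}

#' Calibrate group effects against the composite scale
#'
#' Maps the configured global composite deficits (SD units on the
#' pooled-standardized one-factor composite) to per-measure mean shifts
#' whose pattern follows the configured deficit profiles, using a
#' closed-form fixed-point iteration on the population measure covariance:
#' the pooled correlation matrix implied by candidate shifts (including the
#' between-group variance the pooled rank-normalization absorbs) is
#' factored, population one-factor score weights are formed, and the shift
#' scale is updated until the implied standardized composite gaps equal the
#' targets. No simulation is involved; the result is a deterministic
#' function of the configuration.
#'
#' @param config a [generator_config()].
#' @return List with `delta` (35 x groups matrix of per-measure mean
#'   deficits, positive = worse), `factor_shift` (5 x groups matrix of
#'   latent factor-mean shifts carrying the global deficit level) and
#'   `measure_extra` (residual task-specific offsets).
#' @export
calibrate_group_effects <- function(config) {
  catalog <- config$catalog
  L <- config$loadings
  sigma <- L %*% config$phi %*% t(L)
  diag(sigma) <- diag(sigma) + config$psi
  props <- config$n_per_group / sum(config$n_per_group)
  props <- props[GROUP_LEVELS]
  grp <- setdiff(GROUP_LEVELS, "control")

  acc <- catalog_measures(catalog, "accuracy")
  lat <- catalog_measures(catalog, "latency")
  prof_a <- config$accuracy_profile[acc]
  prof_a <- prof_a / mean(prof_a)
  prof_l <- config$latency_profile[lat]
  prof_l <- prof_l / mean(prof_l)

  # Residual group means after the two-step adjustment: fitting the
  # confound model without a group term lets the decade/sex dummies absorb
  # part of the group effect when groups differ demographically. The
  # absorption is a linear map of the true group means, computable from
  # the population cell probabilities of (group, decade, sex, education).
  Cmat <- twostep_absorption(config)

  solve_scale <- function(measures, prof, targets) {
    if (all(targets == 0)) return(outer(prof, targets) * 0)
    S <- sigma[measures, measures]
    a <- targets * 0.7
    a[a == 0] <- 1e-6
    for (it in 1:50) {
      mu <- cbind(control = 0, -outer(prof, a))  # true measure x group means
      mu_obs <- mu %*% t(Cmat)                   # post-adjustment means
      mbar <- as.vector(mu_obs %*% props)
      cen <- mu_obs - mbar
      B <- cen %*% diag(props, 3) %*% t(cen)
      spool <- S + B
      d <- sqrt(diag(spool))
      rpool <- spool / outer(d, d)
      lam <- paf_extract(rpool, 1)$loadings[, 1]
      if (mean(lam) < 0) lam <- -lam
      w <- solve(rpool, lam)
      gaps <- as.vector(t(w) %*% (mu_obs / d))
      sdc <- sqrt(as.numeric(t(w) %*% rpool %*% w))
      est <- (gaps[1] - gaps[-1]) / sdc
      if (max(abs(est - targets)) < 1e-12) break
      a <- a * pmax(targets / est, 0.1)
    }
    -outer(prof, a)  # measure x group mean shifts (negative = deficit)
  }

  delta <- matrix(0, nrow(L), length(grp),
                  dimnames = list(rownames(L), grp))
  delta[acc, ] <- solve_scale(acc, prof_a, config$group_accuracy[grp])
  delta[lat, ] <- solve_scale(lat, prof_l, config$group_latency[grp])

  # Decompose into factor-mean shifts (global level) + per-measure extras.
  factor_shift <- matrix(0, 5, length(grp),
                         dimnames = list(FACTOR_LABELS, grp))
  rs_acc <- rowSums(L[acc, 1:4])
  rs_lat <- L[lat, 5]
  for (g in grp) {
    s_acc <- if (mean(rs_acc) > 0) mean(delta[acc, g]) / mean(rs_acc) else 0
    factor_shift[1:4, g] <- s_acc
    implied_acc <- as.vector(L[lat, 1:4] %*% rep(s_acc, 4))
    factor_shift[5, g] <- if (mean(rs_lat) > 0) {
      mean(delta[lat, g] - implied_acc) / mean(rs_lat)
    } else 0
  }
  extra <- delta - L %*% factor_shift
  list(delta = delta, factor_shift = factor_shift, measure_extra = extra)
}

# 3x3 matrix C mapping true group means to expected residual group means
# after regressing out age decade, sex and education without a group term
# (rows/cols ordered control, PD, RBD). Built from the closed-form joint
# cell distribution implied by the demographic sampling model.
twostep_absorption <- function(config) {
  cells <- expand.grid(group = GROUP_LEVELS, decade = DECADE_LEVELS,
                       sex = SEX_LEVELS, edu = EDUCATION_LEVELS,
                       stringsAsFactors = FALSE)
  p_group <- config$n_per_group[GROUP_LEVELS] /
    sum(config$n_per_group)
  mu <- config$age_means[cells$group]
  sdev <- config$age_sd
  # ages are drawn normal, rounded and clipped to [50, 89]; decade mass
  # follows the normal CDF at the half-integer decade boundaries
  lo <- c(`50s` = -Inf, `60s` = 59.5, `70s` = 69.5, `80s` = 79.5)
  hi <- c(`50s` = 59.5, `60s` = 69.5, `70s` = 79.5, `80s` = Inf)
  p_dec <- pnorm(hi[cells$decade], mu, sdev) -
    pnorm(lo[cells$decade], mu, sdev)
  p_fem <- config$female_frac[cells$group]
  p_sex <- ifelse(cells$sex == "female", p_fem, 1 - p_fem)
  p_edu <- stats::setNames(config$education_probs, EDUCATION_LEVELS)
  w <- p_group[cells$group] * p_dec * p_sex * p_edu[cells$edu]
  w <- as.vector(w / sum(w))

  Z <- stats::model.matrix(
    ~ decade + sex + edu,
    data = data.frame(decade = factor(cells$decade, DECADE_LEVELS),
                      sex = factor(cells$sex, SEX_LEVELS),
                      edu = factor(cells$edu, EDUCATION_LEVELS)))
  G <- stats::model.matrix(
    ~ 0 + group, data = data.frame(group = factor(cells$group,
                                                  GROUP_LEVELS)))
  ZtWZ <- crossprod(Z, w * Z)
  H <- Z %*% solve(ZtWZ, crossprod(Z, w * G))  # projection of group dummies
  grp_mean <- crossprod(G, w * H) / as.vector(crossprod(G, w))
  diag(3) - grp_mean
}
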