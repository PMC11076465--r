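test_that("cross-validation nails noiseless and pure-noise composites", {
  group <- rep(c("control", "PD", "RBD"), each = 40)
  mu <- c(control = 0, PD = -0.65, RBD = -0.45)
  comp <- make_composite(unname(mu[group]), group)
  cv <- crossvalidate_composite_model(comp, scheme = "loo")
  expect_equal(cv$correlation, 1, tolerance = 1e-10)
  expect_equal(cv$mse, 0, tolerance = 1e-20)

  set.seed(81)
  noise <- make_composite(rnorm(500), rep(c("control", "PD", "RBD"),
                                          length.out = 500))
  cvn <- crossvalidate_composite_model(noise, scheme = "kfold", folds = 25,
                                       seed = 3)
  expect_lt(abs(cvn$correlation), 0.1)
})

test_that("leave-one-out equals n-fold cross-validation exactly", {
  set.seed(82)
  group <- rep(c("control", "PD", "RBD"), each = 30)
  comp <- make_composite(rnorm(90) - 0.5 * (group == "PD"), group)
  loo <- crossvalidate_composite_model(comp, scheme = "loo")
  nfold <- crossvalidate_composite_model(comp, scheme = "kfold",
                                         folds = 90, seed = 9)
  expect_equal(loo$predictions$predicted, nfold$predictions$predicted,
               tolerance = 1e-12)
  expect_equal(sort(loo$fold_sizes), sort(nfold$fold_sizes))
})

test_that("held-out responses never leak into their own predictions", {
  set.seed(83)
  group <- rep(c("control", "PD", "RBD"), each = 50)
  comp <- make_composite(rnorm(150), group)
  cv1 <- crossvalidate_composite_model(comp, scheme = "kfold", folds = 5,
                                       seed = 4)
  corrupted <- comp
  fold1 <- cv1$predictions$fold == 1
  corrupted$score[fold1] <- corrupted$score[fold1] + 100
  cv2 <- crossvalidate_composite_model(corrupted, scheme = "kfold",
                                       folds = 5, seed = 4)
  expect_equal(cv2$predictions$predicted[fold1],
               cv1$predictions$predicted[fold1], tolerance = 1e-12)
})

test_that("cross-validated MSE estimates the injected noise variance", {
  set.seed(84)
  group <- rep(c("control", "PD", "RBD"), length.out = 1000)
  mu <- c(control = 0, PD = -0.65, RBD = -0.45)
  sigma2 <- 0.49
  comp <- make_composite(unname(mu[group]) + rnorm(1000, sd = sqrt(sigma2)),
                         group)
  cv <- crossvalidate_composite_model(comp, scheme = "kfold", folds = 25,
                                      seed = 5)
  expect_equal(cv$mse, sigma2, tolerance = 0.1 * sigma2)
})

test_that("model variants agree when age effects are benign", {
  cfg <- generator_config(n_per_group = c(control = 200, PD = 200,
                                          RBD = 200), n_per_decade = 50)
  gen <- generate_cohort(cfg, seed = 85)
  measures <- c("blocks.primary", "word_definitions.primary",
                "srt.primary")
  for (v in c("one_model", "continuous_age_cubic")) {
    res <- model_variant_contrasts(gen$cohort, v, measures = measures)
    expect_lt(res$agreement$max_abs_delta_smd, 0.15)
    expect_equal(res$agreement$sign_agreement, 1)
    expect_equal(unique(res$contrasts$variant), v)
  }
})

test_that("a strong within-decade age trend is removed only by the cubic model", {
  cfg <- null_config(500)
  gen <- generate_cohort(cfg, seed = 86)
  cohort <- gen$cohort
  # inject a steep continuous age effect, invisible to decade dummies
  # within decades; groups differ in age so decades leave residual bias
  age_c <- (cohort$age_years - 70) / 10
  cohort$blocks.primary <- cohort$blocks.primary +
    1.5 * age_c + 0.8 * age_c^3
  cubic <- model_variant_contrasts(cohort, "continuous_age_cubic",
                                   measures = "blocks.primary")
  # the primary (decade-based) analysis shows residual confounding that
  # the continuous cubic variant removes
  expect_gt(cubic$agreement$max_abs_delta_smd, 0.02)
  expect_lt(max(abs(cubic$contrasts$smd)), 0.12)
})

test_that("subgroups partition PD and respect the RBDSQ cutoff", {
  cfg <- generator_config(n_per_group = c(control = 300, PD = 400,
                                          RBD = 300), n_per_decade = 50)
  gen <- generate_cohort(cfg, seed = 87)
  cohort <- gen$cohort
  expect_equal(sum(cohort$probable_rbd[cohort$group == "PD"]) +
                 sum(!cohort$probable_rbd[cohort$group == "PD"]),
               sum(cohort$group == "PD"))
  adj <- adjust_all(cohort)
  comps <- list(
    accuracy = global_composite(adj, catalog_measures(task_catalog(),
                                                      "accuracy")),
    latency = global_composite(adj, catalog_measures(task_catalog(),
                                                     "latency")))
  res <- subgroup_contrasts(cohort, comps)
  lat <- res[res$comparison == "PD+RBD vs PD-RBD" &
               res$composite == "latency", ]
  acc <- res[res$comparison == "PD+RBD vs PD-RBD" &
               res$composite == "accuracy", ]
  # the probable-RBD subgroup is slower (deficit oriented high = good)
  expect_lt(lat$smd, 0)
  expect_lt(lat$p_value, 0.05)
  expect_lt(acc$smd, 0)  # milder accuracy trend, same direction
  expect_gt(acc$p_value, lat$p_value)
})

test_that("empty subgroups are skipped with a warning", {
  cfg <- small_config(60)
  cfg$rbd_subgroup$pd_probable_fraction <- 0
  cfg$rbdsq_low_mean[] <- 1  # keep everyone under the cutoff
  gen <- generate_cohort(cfg, seed = 88)
  gen$cohort$probable_rbd <- FALSE
  adj <- adjust_all(gen$cohort)
  comps <- list(accuracy = global_composite(
    adj, catalog_measures(task_catalog(), "accuracy")))
  expect_warning(res <- subgroup_contrasts(gen$cohort, comps), "skipped")
  expect_false(any(grepl("PD\\+RBD", res$comparison)))
})

test_that("motor correlations recover anchors and generator coupling", {
  set.seed(89)
  n <- 200
  cohort <- tibble::tibble(
    participant_id = sprintf("P%04d", 1:n), group = "PD",
    updrs3 = rnorm(n, 30, 10),
    updrs3_ft_hand1 = sample(0:4, n, TRUE),
    updrs3_ft_hand2 = sample(0:4, n, TRUE),
    updrs3_ft_hand3 = sample(0:4, n, TRUE),
    updrs3_ft_hand4 = sample(0:4, n, TRUE))
  comp_anti <- make_composite(-cohort$updrs3, rep("PD", n),
                              participant_id = cohort$participant_id)
  res <- motor_confound_correlation(cohort, list(anti = comp_anti))
  expect_equal(res$r[res$motor_measure == "updrs3"], -1,
               tolerance = 1e-10)
  comp_null <- make_composite(rnorm(n), rep("PD", n),
                              participant_id = cohort$participant_id)
  res0 <- motor_confound_correlation(cohort, list(null = comp_null))
  expect_lt(max(abs(res0$r)), 0.15)

  cfg <- generator_config(n_per_group = c(control = 100, PD = 400,
                                          RBD = 100), n_per_decade = 50)
  gen <- generate_cohort(cfg, seed = 90)
  adj <- adjust_all(gen$cohort)
  lat <- global_composite(adj, catalog_measures(task_catalog(), "latency"))
  resc <- motor_confound_correlation(gen$cohort, list(latency = lat))
  r_updrs <- resc$r[resc$motor_measure == "updrs3"]
  expect_lt(abs(abs(r_updrs) - 0.4), 0.1)
  expect_lt(r_updrs, 0)
})
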