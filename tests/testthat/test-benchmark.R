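test_that("scale prediction recovers exact and null fits", {
  set.seed(71)
  x <- matrix(rnorm(1000 * 3), ncol = 3,
              dimnames = list(NULL, paste0("m", 1:3)))
  adj <- make_adjusted(x, rep("control", 1000))
  y <- 2 * x[, 1] - x[, 2] + 0.5 * x[, 3]
  fit <- predict_scale_from_tasks(adj, paste0("m", 1:3), y)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  fit0 <- predict_scale_from_tasks(adj, paste0("m", 1:3), rnorm(1000))
  expect_lt(fit0$r_squared, 0.05)
  expect_error(predict_scale_from_tasks(adj, paste0("m", 1:3),
                                        c(y[1:3], rep(NA, 997))),
               class = "cb_benchmark_error")
})

test_that("collinear predictors trigger a warning", {
  set.seed(72)
  x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  x[, 2] <- x[, 1]
  adj <- make_adjusted(x, rep("control", 100))
  expect_warning(predict_scale_from_tasks(adj, c("a", "b"), rnorm(100)),
                 "collinear")
})

test_that("task-scale correlations hit the exact anchors", {
  set.seed(73)
  s <- rnorm(100)
  x <- cbind(same = s, anti = -s, noise = rnorm(100))
  adj <- make_adjusted(x, rep("control", 100))
  res <- task_scale_correlations(adj, s)
  expect_equal(res$r[res$measure_id == "same"], 1, tolerance = 1e-10)
  expect_equal(res$r[res$measure_id == "anti"], -1, tolerance = 1e-10)
  expect_lt(abs(res$r[res$measure_id == "noise"]), 0.3)

  x2 <- cbind(sparse = c(s[1:2], rep(NA, 98)))
  adj2 <- make_adjusted(x2, rep("control", 100))
  expect_warning(out <- task_scale_correlations(adj2, s), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("composite-scale correlation squares to the regression R^2", {
  gen <- generate_cohort(small_config(150), seed = 74)
  adj <- adjust_all(gen$cohort)
  comp <- global_composite(adj, catalog_measures(task_catalog(),
                                                 "accuracy"))
  sv <- adjust_scale(gen$cohort, "moca_total.assessment")$scores[, 1]
  idx <- match(comp$participant_id, gen$cohort$participant_id)
  keep <- !is.na(sv[idx])
  r <- cor(comp$score[keep], sv[idx][keep])
  fit <- summary(lm(sv[idx][keep] ~ comp$score[keep]))
  expect_equal(r^2, fit$r.squared, tolerance = 1e-10)
})

test_that("subscale regression handles exact, null and sparse cases", {
  set.seed(75)
  sub <- data.frame(participant_id = sprintf("P%04d", 1:300),
                    s1 = sample(0:3, 300, TRUE),
                    s2 = sample(0:2, 300, TRUE))
  comp <- make_composite(2 * sub$s1 - 1, rep("control", 300),
                         participant_id = sub$participant_id)
  fit <- predict_composite_from_subscales(comp, sub)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  comp0 <- make_composite(rnorm(300), rep("control", 300),
                          participant_id = sub$participant_id)
  fit0 <- predict_composite_from_subscales(comp0, sub)
  k <- fit0$n_predictors
  expect_lt(fit0$r_squared, 4 * k / 299)

  sub$s1[1] <- 9  # singleton level gets merged
  expect_warning(predict_composite_from_subscales(comp0, sub), "merged")
})

test_that("ceiling compression attenuates scale discriminability", {
  set.seed(76)
  n <- 400
  group <- rep(c("control", "PD"), each = n)
  latent <- rnorm(2 * n) - 0.65 * (group == "PD")
  cov <- data.frame(participant_id = sprintf("P%04d", 1:(2 * n)),
                    group = group, age_years = 65,
                    sex = rep(c("male", "female"), n),
                    education_band = "5-10y",
                    raw = 27 + 1.8 * latent,
                    ceilinged = pmin(round(27 + 1.8 * latent), 28))
  cohort <- as_cohort(cov)
  raw_smd <- scale_group_discriminability(
    adjust_scale(cohort, "raw", covariates = "sex"))$smd
  ceil_smd <- scale_group_discriminability(
    adjust_scale(cohort, "ceilinged", covariates = "sex"))$smd
  expect_lt(abs(ceil_smd), abs(raw_smd))
  expect_equal(abs(raw_smd), 0.65, tolerance = 0.12)
})

test_that("paired change test matches its closed form", {
  res <- paired_change_test(c(26, 27, 28, 29), c(26, 27, 28, 29),
                            rep("PD", 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(77)
  base <- rnorm(30, 27, 2)
  follow <- base + 0.8 + rnorm(30, sd = 0.5)
  res <- paired_change_test(base, follow, rep("PD", 30),
                            interval_years = rep(6.5, 30))
  d <- follow - base
  t_oracle <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$mean_interval, 6.5)

  follow[2] <- NA
  res2 <- paired_change_test(base, follow, rep("PD", 30))
  expect_equal(res2$n_dropped, 1)
})

test_that("benchmark statistics are invariant to affine scale rescaling", {
  gen <- generate_cohort(small_config(120), seed = 78)
  cohort <- gen$cohort
  a1 <- adjust_scale(cohort, "moca_total.assessment")
  cohort2 <- cohort
  cohort2$moca_total.assessment <- 3 * cohort$moca_total.assessment + 7
  a2 <- adjust_scale(cohort2, "moca_total.assessment")
  expect_equal(a1$scores[, 1], a2$scores[, 1], tolerance = 1e-12)
})

test_that("the full benchmark bundle reproduces its component pieces", {
  cfg <- generator_config(n_per_group = c(control = 150, PD = 150,
                                          RBD = 150), n_per_decade = 50)
  gen <- generate_cohort(cfg, seed = 79)
  adj <- adjust_all(gen$cohort)
  cat19 <- task_catalog()
  bm <- catalog_measures(cat19[cat19$final_battery_member, ], "primary")
  comp <- global_composite(adj, bm, "reduced_battery")
  rep <- benchmark_scale(gen$cohort, adj, comp, bm, scale = "moca")
  expect_true(rep$scale_from_tasks$r_squared > 0 &&
                rep$scale_from_tasks$r_squared < 1)
  expect_lt(rep$scale_from_tasks$p_value, 0.05)
  expect_gt(rep$composite_scale_r, 0.2)
  expect_equal(nrow(rep$task_correlations), length(bm))
  expect_lt(rep$composite_from_subscales$p_value, 0.05)
  expect_equal(sort(rep$paired_change$group),
               c("PD", "RBD", "control"))
  # word knowledge correlates with the scale more than face emotion
  wd <- rep$task_correlations$r[
    rep$task_correlations$measure_id == "word_definitions.primary"]
  em <- rep$task_correlations$r[
    rep$task_correlations$measure_id ==
      "emotional_discrimination.primary"]
  expect_gt(wd, em)
})
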