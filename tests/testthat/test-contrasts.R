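test_that("group contrast handles identical and constructed gaps", {
  adj <- make_adjusted(matrix(1, 20, 1, dimnames = list(NULL, "m")),
                       rep(c("control", "PD"), each = 10))
  res <- group_contrast(adj, "m", groups = "PD")
  expect_equal(res$smd, 0)
  expect_equal(res$p_value, 1)

  set.seed(41)
  n <- 1e5
  x <- c(rnorm(n), rnorm(n, -0.5))
  adj <- make_adjusted(matrix(x, dimnames = list(NULL, "m")),
                       rep(c("control", "PD"), each = n))
  res <- group_contrast(adj, "m", groups = "PD")
  expect_equal(res$smd, -0.5, tolerance = 0.02)
  expect_lt(res$p_value, 1e-10)
})

test_that("group contrast matches the closed-form two-group OLS oracle", {
  a <- c(1, 2, 3)          # control
  b <- c(3, 5, 7)          # PD
  adj <- make_adjusted(matrix(c(a, b), dimnames = list(NULL, "m")),
                       rep(c("control", "PD"), each = 3))
  res <- group_contrast(adj, "m", groups = "PD")
  # hand-computed: coefficient = mean(b) - mean(a); pooled-variance se;
  # two-sided p from t with 4 df
  coef_oracle <- mean(b) - mean(a)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 4
  se_oracle <- sqrt(s2 * (1 / 3 + 1 / 3))
  t_oracle <- coef_oracle / se_oracle
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(res$smd, coef_oracle, tolerance = 1e-12)
  expect_equal(res$se, se_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("a requested group that is absent raises an error", {
  adj <- make_adjusted(matrix(rnorm(10), dimnames = list(NULL, "m")),
                       rep("control", 10))
  expect_error(group_contrast(adj, "m", groups = "PD"),
               class = "cb_contrast_error")
})

test_that("two-way ANOVA partitions a balanced 2x2 toy exactly", {
  # cell means: (g1,t1)=2, (g1,t2)=4, (g2,t1)=6, (g2,t2)=12; 2 obs/cell
  d <- data.frame(
    group = rep(c("g1", "g1", "g2", "g2"), each = 2),
    task = rep(c("t1", "t2", "t1", "t2"), each = 2),
    value = c(1, 3, 3, 5, 5, 7, 11, 13))
  res <- two_way_anova(d)
  # textbook partition: SS_group = 8*(mean_g - grand)^2 summed, etc.
  grand <- mean(d$value)
  ss_group <- 4 * sum((tapply(d$value, d$group, mean) - grand)^2)
  ss_task <- 4 * sum((tapply(d$value, d$task, mean) - grand)^2)
  cellm <- tapply(d$value, interaction(d$group, d$task), mean)
  ss_cells <- 2 * sum((cellm - grand)^2)
  ss_int <- ss_cells - ss_group - ss_task
  tab <- res$table
  expect_equal(tab$sum_sq[tab$term == "group"], ss_group, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "task"], ss_task, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "group:task"], ss_int,
               tolerance = 1e-8)
})

test_that("two-way ANOVA handles degenerate and malformed input", {
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  task = rep(c("t1", "t2"), 4), value = 1)
  res <- two_way_anova(d)
  expect_true(res$zero_variance)
  expect_equal(res$table$statistic, c(0, 0, 0))
  expect_equal(res$table$p_value, c(1, 1, 1))

  d2 <- data.frame(group = c("a", "a", "b", "b"),
                   task = c("t1", "t2", "t1", "t1"),
                   value = rnorm(4))
  err <- expect_error(two_way_anova(d2), class = "cb_contrast_error")
  expect_match(conditionMessage(err), "b:t2")
})

test_that("Tukey pairwise differences are mutually consistent", {
  gen <- generate_cohort(small_config(60), seed = 42)
  adj <- adjust_all(gen$cohort)
  long <- stack_adjusted(adj, catalog_measures(task_catalog(), "primary"))
  res <- two_way_anova(long)
  tk <- res$tukey
  d <- setNames(tk$difference, tk$comparison)
  expect_equal(unname(d["RBD-control"] - d["PD-control"]),
               unname(d["RBD-PD"]), tolerance = 1e-10)
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))
  expect_true(all(res$table$sum_sq >= 0))
})

test_that("age-decade contrasts recover injected monotone decline", {
  cfg <- null_config()
  cfg$n_per_decade <- 5000
  inj <- matrix(0, 35, 4, dimnames = list(rownames(cfg$loadings),
                                          c("50s", "60s", "70s", "80s")))
  inj["blocks.primary", ] <- -0.2 * (0:3)
  cfg$age_measure_offsets <- inj
  norm <- generate_normative_sample(cfg, seed = 43)
  adj <- adjust_all(norm, covariates = c("sex", "education_band"))
  res <- age_decade_contrast(adj, "blocks.primary")
  expect_equal(res$smd, c(-0.2, -0.4, -0.6), tolerance = 0.05)

  null_res <- age_decade_contrast(adj, "digit_span.primary")
  expect_lt(max(abs(null_res$smd)), 0.05)

  few <- adj
  few$participants <- few$participants[few$participants$age_decade != "80s", ]
  few$scores <- few$scores[adj$participants$age_decade != "80s", ]
  expect_error(age_decade_contrast(few, "blocks.primary"),
               class = "cb_contrast_error")
})

test_that("age-related word-knowledge gain opposes the patient deficit", {
  cfg <- generator_config(n_per_group = c(control = 400, PD = 400,
                                          RBD = 400), n_per_decade = 1000)
  gen <- generate_cohort(cfg, seed = 44)
  adj <- adjust_all(gen$cohort)
  pat <- group_contrast(adj, "word_definitions.primary")
  expect_lt(pat$smd[pat$contrast == "PD-control"], 0)

  norm <- generate_normative_sample(cfg, seed = 45)
  nadj <- adjust_all(norm, covariates = c("sex", "education_band"))
  aging <- age_decade_contrast(nadj, "word_definitions.primary")
  expect_gt(aging$smd[aging$contrast == "80s-50s"], 0)
})

test_that("orientation equivariance: flipping a latency measure flips its contrast", {
  cfg <- small_config(200)
  gen <- generate_cohort(cfg, seed = 46)
  adj <- adjust_all(gen$cohort)
  res <- group_contrast(adj, "srt.primary")

  flipped <- gen$cohort
  flipped$srt.primary <- -flipped$srt.primary  # now lower = better
  attr(flipped, "latency_oriented") <- FALSE   # catalog orientation applies
  adj2 <- adjust_all(flipped)
  res2 <- group_contrast(adj2, "srt.primary")
  expect_equal(res2$smd, res$smd, tolerance = 1e-10)
})

test_that("effect sizes bin by Sawilowsky thresholds, inclusive upward", {
  expect_equal(effect_size_label(0.65), "medium")
  expect_equal(effect_size_label(0), "negligible")
  expect_equal(effect_size_label(1.2), "very large")
  expect_equal(effect_size_label(c(-0.5, 0.09, 0.2, 2.5)),
               c("medium", "negligible", "small", "huge"))
  expect_error(effect_size_label(Inf), class = "cb_contrast_error")
})
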