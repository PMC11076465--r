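covars <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    age_decade = factor(sample(c("50s", "60s", "70s", "80s"), n, TRUE),
                        levels = c("50s", "60s", "70s", "80s")),
    sex = factor(sample(c("male", "female"), n, TRUE),
                 levels = c("male", "female")),
    education_band = factor(sample(c("none", "<5y", "5-10y", ">10y"), n,
                                   TRUE),
                            levels = c("none", "<5y", "5-10y", ">10y")))
}

test_that("confound model recovers exact, null and analytic R-squared", {
  cv <- covars(400)
  y <- 2 + 1.5 * (cv$sex == "female")
  m <- fit_confound_model(y, cv)
  expect_equal(m$r_squared, 1)
  expect_equal(max(abs(residualize(m, cv, y))), 0, tolerance = 1e-10)

  cv <- covars(5000, seed = 2)
  set.seed(3)
  y <- rnorm(5000)
  expect_lt(fit_confound_model(y, cv)$r_squared, 0.01)

  # y = 0.3 * decade index + N(0,1): R^2 -> 0.09 var(idx) / (0.09 var + 1)
  cv <- covars(4000, seed = 4)
  idx <- as.integer(cv$age_decade) - 1
  set.seed(5)
  y <- 0.3 * idx + rnorm(4000)
  expected <- 0.09 * var(idx) / (0.09 * var(idx) + 1)
  expect_lt(abs(fit_confound_model(y, cv)$r_squared - expected), 0.02)
})

test_that("confound model rejects degenerate inputs by name", {
  cv <- covars(50)
  cv$sex <- factor("male", levels = c("male", "female"))
  err <- expect_error(fit_confound_model(rnorm(50), cv),
                      class = "cb_adjustment_error")
  expect_match(conditionMessage(err), "female")
  expect_error(fit_confound_model(rep(1, 50), covars(50)),
               class = "cb_adjustment_error")
})

test_that("residualize handles held-out rows, missingness and new levels", {
  cv <- covars(200, seed = 6)
  set.seed(7)
  y <- 0.5 * (cv$sex == "female") + rnorm(200)
  m <- fit_confound_model(y[1:150], cv[1:150, ])
  held <- residualize(m, cv[151:200, ], y[151:200])
  expect_lt(abs(mean(held)), 3 / sqrt(50))

  y2 <- y
  y2[3] <- NA
  expect_identical(is.na(residualize(m, cv, y2)), is.na(y2))

  cv2 <- cv
  cv2$sex <- as.character(cv2$sex)
  cv2$sex[1] <- "other"
  err <- expect_error(residualize(m, cv2, y), class = "cb_adjustment_error")
  expect_match(conditionMessage(err), "other")

  m0 <- fit_confound_model(y, data.frame(one = factor(rep(c("a", "b"),
                                                          100))),
                           terms = "one")
  # intercept-plus-balanced-dummy model: residuals are group-mean centred
  grand <- residualize(m0, data.frame(one = factor(rep("a", 200),
                                                   levels = c("a", "b"))),
                       y)
  expect_equal(grand, y - mean(y[rep(c(TRUE, FALSE), 100)]),
               tolerance = 1e-10)
})

test_that("rank-INT maps ranks to normal quantiles with Blom offset", {
  expect_equal(rank_inverse_normal(c(10, 20, 30))[2], 0)
  x <- c(5, 1, 9, 3)
  r <- rank(x)
  oracle <- qnorm((r - 3 / 8) / (4 + 1 / 4))
  expect_equal(rank_inverse_normal(x), oracle, tolerance = 1e-12)

  set.seed(8)
  y <- rnorm(101)
  expect_equal(rank_inverse_normal(-y), -rank_inverse_normal(y),
               tolerance = 1e-12)
  # monotone invariance
  expect_equal(rank_inverse_normal(exp(y)), rank_inverse_normal(y),
               tolerance = 1e-12)
  # ties get average ranks: symmetric input with ties maps symmetrically
  z <- rank_inverse_normal(c(1, 2, 2, 3))
  expect_equal(z[2], z[3])
  expect_equal(z[2], 0)
  expect_error(rank_inverse_normal(c(1, NA)), class = "cb_adjustment_error")
})

test_that("orientation negates latency and is an involution", {
  expect_equal(orient_scores(c(-1, 0, 1), "lower_better"), c(1, 0, -1))
  expect_equal(orient_scores(c(-1, 0, 1), "higher_better"), c(-1, 0, 1))
  x <- rnorm(5)
  expect_equal(orient_scores(orient_scores(x, "lower_better"),
                             "lower_better"), x)
  expect_error(orient_scores(x, "sideways"), class = "cb_adjustment_error")
})

test_that("adjust_all removes the design and normalizes every column", {
  gen <- generate_cohort(small_config(150), seed = 31)
  adj <- adjust_all(gen$cohort)
  design <- stats::model.matrix(~ age_decade + sex + education_band,
                                data = gen$cohort)[, -1]
  for (m in c("blocks.primary", "srt.primary", "word_definitions.primary")) {
    # OLS residuals are exactly orthogonal to every design column
    res <- residualize(adj$models[[m]], gen$cohort, gen$cohort[[m]])
    keep <- !is.na(res)
    expect_lt(max(abs(cor(design[keep, ], res[keep]))), 1e-10)
    # the rank transform is monotone, so the normalized scores stay
    # essentially uncorrelated with the design
    y <- adj$scores[, m]
    expect_lt(max(abs(cor(design[keep, ], y[keep]))), 0.05)
    # each column is exactly a signed permutation of the normal-score set
    n <- sum(keep)
    expected <- sort(qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4)))
    expect_equal(unname(sort(y[keep])), expected, tolerance = 1e-10)
  }
  expect_true(all(adj$r_squared$r_squared >= 0 &
                    adj$r_squared$r_squared <= 1))
})

test_that("with zero confounds the adjusted scores are rank-identical to raw", {
  cfg <- null_config(120)
  gen <- generate_cohort(cfg, seed = 32)
  adj <- adjust_all(gen$cohort)
  for (m in c("blocks.primary", "digit_span.secondary")) {
    rho <- cor(adj$scores[, m], gen$cohort[[m]], method = "spearman",
               use = "complete.obs")
    # estimated (pure-noise) confound coefficients can swap near-tied
    # ranks, so agreement is near-perfect rather than exact
    expect_gt(rho, 0.98)
  }
})

test_that("adjustment is idempotent on ranks", {
  gen <- generate_cohort(small_config(100), seed = 33)
  adj1 <- adjust_all(gen$cohort)
  cohort2 <- gen$cohort
  for (m in colnames(adj1$scores)) cohort2[[m]] <- adj1$scores[, m]
  attr(cohort2, "latency_oriented") <- TRUE
  adj2 <- adjust_all(cohort2)
  for (m in c("blocks.primary", "srt.primary")) {
    rho <- cor(adj2$scores[, m], adj1$scores[, m], method = "spearman")
    expect_gt(rho, 0.999)
  }
})
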