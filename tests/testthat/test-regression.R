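make_panel <- function(seed = 1, noise_sd = 5.6) {
  simulate_panel(synthetic_spec(seed = seed, noise_sd = noise_sd))
}

test_that("build_design stacks sex strata with the intervention dummy", {
  panel <- make_panel()
  d <- build_design(panel, regression_spec())
  expect_equal(nrow(d$X), 40L)
  expect_equal(colnames(d$X),
               c("(Intercept)", "smoking", "physician", "after_ban"))
  expect_equal(sum(d$X[, "after_ban"]), 9)  # female rows 2012..2020
  expect_true(all(d$rows$group[d$X[, "after_ban"] == 1] == "female"))
  expect_true(all(d$rows$year[d$X[, "after_ban"] == 1] >= 2012))

  nod <- build_design(panel, regression_spec(include_dummy = FALSE))
  expect_equal(colnames(nod$X), c("(Intercept)", "smoking", "physician"))

  expect_error(build_design(panel[panel$group != "female", ],
                            regression_spec()), "not present")
})

test_that("fit_ols recovers exact linear structure and flags singularity", {
  set.seed(5)
  X <- cbind(`(Intercept)` = 1, a = rnorm(30), b = runif(30))
  beta <- c(2, -1.5, 4)
  y <- drop(X %*% beta)
  fit <- fit_ols(X, y)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # outcome orthogonal to a centred covariate -> zero coefficient
  a <- scale(rnorm(40), scale = FALSE)[, 1]
  y2 <- rnorm(40)
  y2 <- y2 - a * sum(a * y2) / sum(a * a)    # project out a
  y2 <- y2 - mean(y2) + 3
  fit2 <- fit_ols(cbind(`(Intercept)` = 1, a = a), y2)
  expect_equal(unname(fit2$coefficients["a"]), 0, tolerance = 1e-10)

  Xs <- cbind(1, a, 2 * a)
  expect_error(fit_ols(Xs, y2), "singular")
})

test_that("R-squared is invariant to affine rescaling of covariates", {
  panel <- make_panel(3)
  d <- build_design(panel, regression_spec())
  r2 <- fit_ols(d$X, d$y)$r_squared
  X2 <- d$X
  X2[, "smoking"] <- 100 * X2[, "smoking"] - 7
  X2[, "physician"] <- 0.2 * X2[, "physician"] + 3
  expect_equal(fit_ols(X2, d$y)$r_squared, r2, tolerance = 1e-12)
})

test_that("bootstrap SEs are deterministic under a seed and vanish without noise", {
  panel <- make_panel(2)
  d <- build_design(panel, regression_spec())
  se1 <- bootstrap_se(d$X, d$y, reps = 200, seed = 99)
  se2 <- bootstrap_se(d$X, d$y, reps = 200, seed = 99)
  expect_identical(se1, se2)
  expect_false(identical(se1,
                         bootstrap_se(d$X, d$y, reps = 200, seed = 100)))

  # exact linear outcome: every resample that fits at all refits exactly
  X <- cbind(1, rep(c(1, 2, 3, 4), 10))
  y <- drop(X %*% c(5, -2))
  se0 <- bootstrap_se(X, y, reps = 100, seed = 1)
  expect_equal(as.numeric(se0), c(0, 0), tolerance = 1e-10)
})

test_that("bootstrap SEs stabilise between 1000 and 10000 replications", {
  panel <- make_panel(4)
  d <- build_design(panel, regression_spec())
  se_1k <- bootstrap_se(d$X, d$y, reps = 1000, seed = 7)
  se_10k <- bootstrap_se(d$X, d$y, reps = 10000, seed = 7)
  expect_true(all(abs(se_1k - se_10k) / se_10k < 0.10))
})

test_that("RESET test reproduces its df structure and a known null case", {
  panel <- make_panel(6)
  d3 <- build_design(panel, regression_spec(include_dummy = FALSE))
  rt3 <- reset_test(d3$X, d3$y)
  expect_equal(rt3$df, c(3L, 34L))
  d4 <- build_design(panel, regression_spec())
  rt4 <- reset_test(d4$X, d4$y)
  expect_equal(rt4$df, c(3L, 33L))
  expect_true(rt4$p_value >= 0 && rt4$p_value <= 1)

  # exactly linear outcome: degenerate, no evidence of misspecification
  X <- cbind(1, seq_len(40))
  yl <- drop(X %*% c(3, 0.5))
  rt0 <- reset_test(X, yl)
  expect_true(rt0$degenerate)
  expect_equal(rt0$p_value, 1)

  expect_error(reset_test(X[1:5, ], yl[1:5]), "insufficient")
})

test_that("RESET statistic matches the independent lmtest implementation", {
  skip_if_not_installed("lmtest")
  set.seed(13)
  x1 <- rnorm(40)
  x2 <- rnorm(40)
  y <- 1 + 2 * x1 - x2 + 0.5 * x1^2 + rnorm(40)
  mine <- reset_test(cbind(1, x1 = x1, x2 = x2), y)
  ref <- lmtest::resettest(y ~ x1 + x2, power = 2:4, type = "fitted")
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$df, unname(unlist(ref$parameter)), ignore_attr = TRUE)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("regress_panel returns a coherent result object", {
  panel <- make_panel(8)
  res <- regress_panel(panel, regression_spec(bootstrap_reps = 100,
                                              seed = 3))
  expect_s3_class(res, "regression_result")
  expect_named(res$coefficients,
               c("(Intercept)", "smoking", "physician", "after_ban"))
  expect_equal(res$n_obs, 40L)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)
  expect_equal(length(res$bootstrap_se), length(res$coefficients))
  expect_output(print(res), "Ramsey RESET")
})

test_that("describe_panel reproduces mean, SE and t-based CI", {
  d <- describe_panel(c(27.72, 27.17, 27.01, 29.55))
  expect_equal(round(d$mean, 2), 27.86)
  expect_equal(d$se, sd(c(27.72, 27.17, 27.01, 29.55)) / 2)
  expect_equal(d$ci_upper - d$mean, qt(0.975, 3) * d$se)

  const <- describe_panel(rep(4.2, 6))
  expect_equal(const$se, 0)
  expect_equal(const$ci_lower, 4.2)
  expect_equal(const$ci_upper, 4.2)

  expect_error(describe_panel(5), "at least 2")
})
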