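# core model: lambda_max, standardization, deviances, the penalized fit and
# its grids / cross-validation.

test_that("compute_lambda_max matches direct arithmetic and rejects constant y", {
  d <- labeled_matrix(matrix(c(2, 0), 2, 1), c(1, 0))
  expect_equal(compute_lambda_max(d, standardize = FALSE), 1.0)

  d2 <- labeled_matrix(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
  Xs <- standardize_by_subset(d2, 1:10)$x
  expect_equal(compute_lambda_max(d2), max(abs(crossprod(Xs, d2$y))) / 10)
  expect_gt(compute_lambda_max(d2), 0)

  # constant labels cannot even form the container
  expect_error(labeled_matrix(matrix(rnorm(4), 2, 2), c(0, 0)), "both classes")
})

test_that("standardize_by_subset: subset statistics, zero-sd guard, affine invertibility", {
  d <- toy_data(n = 12, p = 3)
  sb <- standardize_by_subset(d, 1:12)
  expect_equal(colMeans(sb$x), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(sb$x, 2, sd), rep(1, 3), ignore_attr = TRUE)

  # subset statistics only, applied to all rows
  sub <- 1:5
  sb2 <- standardize_by_subset(d, sub)
  expect_equal(colMeans(sb2$x[sub, ]), rep(0, 3), ignore_attr = TRUE)
  expect_equal(sb2$std$means, colMeans(d$X[sub, ]), ignore_attr = TRUE)

  # column constant on the subset but varying off-subset: sd guard 1
  X <- d$X; X[sub, 2] <- 7
  d3 <- labeled_matrix(X, d$y)
  sb3 <- standardize_by_subset(d3, sub)
  expect_equal(sb3$std$sds[2], 1, ignore_attr = TRUE)
  expect_equal(sb3$x[, 2], X[, 2] - 7, ignore_attr = TRUE)

  expect_error(standardize_by_subset(d, integer(0)), "non-empty")
})

test_that("back-transformed coefficients reproduce predictions on the original scale", {
  d <- small_instance(n = 40, p = 10)$data
  sub <- 5:36
  m <- fit_penalized_logistic(d, sub, 0.05, 0.5)
  sb <- standardize_by_subset(d, sub)
  p_std <- plogis(m$intercept + as.numeric(sb$x %*% m$beta))
  p_orig <- predicted_prob(m, d, clip = FALSE)
  expect_equal(p_orig, p_std, tolerance = 1e-10)
})

test_that("per-observation deviance: null model, perfect fit limit, clipping", {
  d <- toy_data(n = 10, p = 2)
  m <- fit_penalized_logistic(d, 1:10, 50, 1) # slopes fully shrunk
  m0 <- m; m0$beta[] <- 0; m0$beta_original[] <- 0
  m0$intercept <- 0; m0$intercept_original <- 0
  expect_equal(per_observation_deviance(m0, d), rep(log(2), 10),
               ignore_attr = TRUE)

  # y = 1 and pi -> 1 gives d -> 0; pre-clip pi ~ 0 caps at -log(1e-10)
  m1 <- m0; m1$intercept_original <- 40
  dev1 <- per_observation_deviance(m1, d)
  expect_true(all(dev1[d$y == 1] < 1e-8))
  expect_equal(dev1[d$y == 0], rep(-log(1e-10), sum(d$y == 0)),
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_true(all(is.finite(dev1)) && all(dev1 >= 0))
})

test_that("fit_penalized_logistic matches a generic optimizer of the same objective", {
  set.seed(11)
  d <- toy_data(n = 8, p = 2, seed = 5)
  lam <- 0.05; alpha <- 0.5
  m <- fit_penalized_logistic(d, 1:8, lam, alpha)
  sb <- standardize_by_subset(d, 1:8)
  ora <- optim_en_logistic(sb$x, d$y, lam, alpha,
                           par0 = c(m$intercept, m$beta))
  obj_fit <- -m$loglik_subset + 8 * lam * en_penalty(m$beta, alpha)
  expect_equal(obj_fit, ora$value, tolerance = 1e-6)
  expect_equal(c(m$intercept, m$beta), ora$par, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("heavy penalty gives the null model; degenerate subsets error", {
  d <- small_instance(n = 50, p = 15)$data
  sub <- 1:40
  # at a lambda at/above the logistic path's own sparsity point all slopes
  # vanish and the intercept is the subset log-odds
  sb <- standardize_by_subset(d, sub)
  ybar <- mean(d$y[sub])
  lam_sp <- max(abs(crossprod(sb$x[sub, ], d$y[sub] - ybar))) / length(sub)
  m <- fit_penalized_logistic(d, sub, lam_sp * 1.01, 1)
  expect_equal(sum(m$beta != 0), 0)
  expect_equal(m$intercept, qlogis(ybar), tolerance = 1e-6)

  expect_error(fit_penalized_logistic(d, which(d$y == 1), 0.1, 0.5),
               "degenerate subset")
})

test_that("deviance/likelihood duality and objective decrease versus the null", {
  d <- small_instance(n = 40, p = 12, seed = 9)$data
  for (lam in c(0.01, 0.1)) {
    m <- fit_penalized_logistic(d, 1:40, lam, 0.5)
    expect_equal(m$loglik_subset, -sum(m$deviances_full[1:40]),
                 tolerance = 1e-8)
    obj <- -m$loglik_subset + 40 * lam * en_penalty(m$beta, 0.5)
    obj_null <- -40 * (mean(d$y[1:40]) * log(mean(d$y[1:40])) +
                       (1 - mean(d$y[1:40])) * log(1 - mean(d$y[1:40])))
    expect_lte(obj, obj_null + 1e-8)
    expect_true(all(m$deviances_full >= 0))
  }
})

test_that("sparsity is monotone along increasing lambda at alpha = 1", {
  d <- small_instance(n = 50, p = 30, seed = 4)$data
  lm <- compute_lambda_max(d)
  sizes <- vapply(seq(0.05, 1, by = 0.05) * lm, function(l) {
    sum(fit_penalized_logistic(d, 1:50, l, 1)$beta != 0)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("build_grids: iteration and refit contracts", {
  g <- build_grids(0.8, "iteration")
  expect_length(g$lambda_fractions, 20)
  expect_equal(g$alphas, 0.5)
  expect_equal(g$lambda_fractions, seq(0.05, 1, by = 0.05))

  r <- build_grids(0.8, "refit")
  expect_length(r$lambda_fractions, 100)
  expect_length(r$alphas, 10)

  for (gr in list(g, r)) {
    lams <- gr$lambda_fractions * gr$lambda_max
    expect_true(all(lams > 0 & lams <= gr$lambda_max + 1e-12))
  }
  expect_error(build_grids(-1), "lambda_max")
  expect_error(reg_grid(1, c(0.5, 0.2, 1), 0.5), "increasing")
})

test_that("cv_select: determinism, singleton grid, and signal detection", {
  ds <- small_instance(n = 60, p = 20, seed = 2)
  d <- ds$data
  lm <- compute_lambda_max(d)
  g <- build_grids(lm, "iteration")
  s1 <- cv_select(d, 1:60, g, seed = 123)
  s2 <- cv_select(d, 1:60, g, seed = 123)
  expect_identical(s1[c("lam", "alpha")], s2[c("lam", "alpha")])

  single <- reg_grid(lm, 1, 0.7)
  s3 <- cv_select(d, 1:60, single, seed = 1)
  expect_equal(s3$lam, lm)
  expect_equal(s3$alpha, 0.7)

  # strong signal: some variable enters, so the winner sits below lambda_max
  expect_lt(s1$lam, lm)

  # too-small subset: folds reduced with a warning, minimum 2
  sub <- c(which(d$y == 1)[1:3], which(d$y == 0)[1:3])
  expect_warning(s4 <- cv_select(d, sub, g, folds = 5, seed = 1),
                 "reducing folds")
  expect_equal(s4$folds, 3)
})
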