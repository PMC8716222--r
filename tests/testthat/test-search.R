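# search algorithms: C-step, grid C-step, acceptance-rejection C-step,
# multi-start, exhaustive oracle.

test_that("cstep_fixed is monotone and a fixed point of the oracle optimum", {
  ds <- oracle_instance(n = 12, p = 3, seed = 3)
  d <- ds$data
  plan <- plan_for_data(d)
  lam <- 0.1 * compute_lambda_max(d)

  ora <- exhaustive_oracle(d, plan, lam, 0.5)
  res <- cstep_fixed(d, ora$H, lam, 0.5, plan)
  expect_identical(res$state$H, ora$H)
  expect_equal(res$state$Q, ora$Q, tolerance = 1e-8)
  expect_lte(nrow(res$trace), 2) # converges immediately

  set.seed(31)
  res2 <- cstep_fixed(d, six_start(d), lam, 0.5, plan)
  q <- res2$trace$Q[res2$trace$size == plan$h]
  expect_true(all(diff(q) <= 1e-9))
  expect_true(attr(res2$trace, "converged"))
})

test_that("cstep_fixed satisfies both Eq-chain inequalities at every step", {
  set.seed(77)
  ds <- small_instance(n = 60, p = 20, seed = 14)
  d <- ds$data
  plan <- plan_for_data(d)
  lam <- 0.1 * compute_lambda_max(d)
  res <- cstep_fixed(d, six_start(d), lam, 0.5, plan)
  tr <- res$trace[res$trace$size == plan$h, ]
  # candidate under current fit never worse than current subset under it
  expect_true(all(tr$Q_cand_under_cur <= tr$Q + 1e-9))
  # refit never worse than the candidate under the previous fit
  if (nrow(tr) > 1) {
    expect_true(all(tr$Q[-1] <= tr$Q_cand_under_cur[-nrow(tr)] + 1e-8))
  }
})

test_that("cstep_grid: argmin contract and singleton-grid reduction", {
  ds <- oracle_instance(n = 12, p = 3, seed = 6)
  d <- ds$data
  plan <- plan_for_data(d)
  lm <- compute_lambda_max(d)
  set.seed(9)
  starts <- lapply(1:3, function(i) six_start(d))

  g <- reg_grid(lm, c(0.25, 0.5, 1), c(0.5, 1))
  best <- cstep_grid(d, starts, g, plan)
  expect_equal(attr(best, "run_count"), 3 * 2 * 3)

  # every per-combination, per-start rerun is no better
  std <- standardize_by_subset(d, 1:12)$std
  for (a in g$alphas) for (f in g$lambda_fractions) for (H0 in starts) {
    r <- cstep_fixed(d, H0, f * lm, a, plan, standardization = std)
    expect_gte(r$state$Q, best$Q - 1e-9)
  }

  single <- reg_grid(lm, 1, 0.5)
  b1 <- cstep_grid(d, starts[1], single, plan)
  r1 <- cstep_fixed(d, starts[[1]], lm, 0.5, plan)
  expect_equal(b1$Q, r1$state$Q, tolerance = 1e-10)
  expect_identical(b1$H, r1$state$H)
})

test_that("acceptance probability follows the printed law", {
  expect_equal(acceptance_probability(-5, -1, k = 0, D = 2.5), 1)
  expect_equal(acceptance_probability(-3, -3, k = 7, D = 2.5), 1)
  # D = 0.1 * 100 * 0.25 = 2.5; k = 9, delta = -1
  expect_equal(acceptance_probability(-11, -10, 9, 2.5),
               exp(-log(10) / 2.5), tolerance = 1e-9)
  expect_equal(acceptance_probability(-11, -10, 9, 2.5), 0.398, tolerance = 1e-3)
  # strictly decreasing in k at fixed deficit
  ps <- vapply(0:20, function(k) acceptance_probability(-11, -10, k, 2.5),
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_error(acceptance_probability(-1, -1, 1, 0), "D")
})

test_that("ar_cstep_run: Q_opt non-increasing, stall stop, opt returned", {
  ds <- small_instance(n = 60, p = 20, seed = 5)
  d <- ds$data
  plan <- plan_for_data(d)
  g <- build_grids(compute_lambda_max(d), "iteration")
  cfg <- ar_cstep_config(seed = 1, folds = 3)
  set.seed(42)
  res <- suppressWarnings(
    ar_cstep_run(d, six_start(d), plan, g, cfg)
  )
  expect_true(all(diff(res$trace$Q_opt) <= 1e-12))
  expect_true(attr(res$trace, "stopped") %in% c("stalled", "max_iter"))
  expect_equal(res$state$Q, min(res$trace$Q_opt), tolerance = 1e-10)
  expect_length(res$state$H, plan$h)
  # whenever the candidate did not worsen Q, acceptance was certain
  ok <- res$trace$Q_cand <= res$trace$Q_before
  expect_true(all(res$trace$p_accept[ok] == 1))
  expect_true(all(res$trace$accepted[ok]))
})

test_that("multi_start_search: start composition, reduction, argmin contract", {
  ds <- small_instance(n = 40, p = 10, seed = 12)
  d <- ds$data
  plan <- plan_for_data(d)
  g <- build_grids(compute_lambda_max(d), "iteration")

  # n_starts = 1, keep = 1 reduces to one ar_cstep_run from that start
  cfg1 <- ar_cstep_config(n_starts = 1, keep = 1, seed = 99, folds = 3)
  best1 <- suppressWarnings(multi_start_search(d, plan, g, cfg1))
  expect_s3_class(best1, "subset_state")
  # the single start drawn under seed 99 is a 3 + 3 stratified sextet
  set.seed(99)
  H0 <- sort(c(sample(which(d$y == 1L), 3), sample(which(d$y == 0L), 3)))
  expect_length(H0, 6)
  expect_equal(sum(d$y[H0]), 3)

  cfg <- ar_cstep_config(n_starts = 12, keep = 4, seed = 7, folds = 3)
  best <- suppressWarnings(multi_start_search(d, plan, g, cfg))
  expect_s3_class(best, "subset_state")
  expect_length(best$H, plan$h)
  kept <- attr(best, "kept_Q")
  expect_length(kept, 4)
  expect_equal(best$Q, min(kept), tolerance = 1e-10)
  expect_length(attr(best, "warm_Q"), 12)
  expect_gt(attr(best, "fit_count"), 0)

  # determinism: same config, same result
  best_b <- suppressWarnings(multi_start_search(d, plan, g, cfg))
  expect_identical(best$H, best_b$H)
  expect_equal(best$Q, best_b$Q)

  d_small <- labeled_matrix(matrix(rnorm(20), 10, 2),
                            c(1, 1, rep(0, 8)))
  expect_error(multi_start_search(d_small, make_plan(2, 8, 0.8), g, cfg),
               "too few samples")
})

test_that("exhaustive_oracle: enumeration count, dominance, determinism", {
  ds <- oracle_instance(n = 10, p = 2, seed = 4)
  d <- ds$data
  plan <- plan_for_data(d, 0.8)
  lam <- 0.1 * compute_lambda_max(d)
  ora <- exhaustive_oracle(d, plan, lam, 0.5)
  expect_equal(attr(ora, "n_subsets"),
               choose(d$n1, plan$h1) * choose(d$n0, plan$h0))
  expect_length(ora$H, plan$h)
  expect_equal(sum(d$y[ora$H]), plan$h1)

  ora2 <- exhaustive_oracle(d, plan, lam, 0.5)
  expect_identical(ora$H, ora2$H) # deterministic

  set.seed(13)
  for (i in 1:5) {
    r <- cstep_fixed(d, six_start(d), lam, 0.5, plan)
    expect_gte(r$state$Q, ora$Q - 1e-9)
  }

  big <- small_instance(n = 60, p = 5)$data
  expect_error(exhaustive_oracle(big, plan_for_data(big), lam, 0.5),
               "guard")
})

test_that("search traces export as JSON lines", {
  ds <- oracle_instance(n = 12, p = 3, seed = 3)
  d <- ds$data
  plan <- plan_for_data(d)
  set.seed(2)
  res <- cstep_fixed(d, six_start(d), 0.05, 0.5, plan)
  path <- tempfile(fileext = ".jsonl")
  write_trace_jsonl(res$trace, path)
  lines <- readLines(path)
  expect_length(lines, nrow(res$trace))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("iter", "Q") %in% names(rec)))
})
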