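## Subset-search algorithms.
##
## cstep_fixed      : classic concentration step at fixed (lambda, alpha);
##                    the two-sided inequality chain guarantees a
##                    non-increasing criterion, so the standardization is held
##                    fixed (full-data statistics by default) to keep Q values
##                    exactly comparable across iterations.
## cstep_grid       : cstep_fixed run to convergence for every (lambda, alpha)
##                    combination -- the expensive baseline.
## ar_cstep_run     : the acceptance-rejection C-step. Regularization may be
##                    re-selected by cross-validation at every fit, so the
##                    criterion can increase; a worse candidate subset is
##                    accepted with a Metropolis-type probability and the best
##                    state ever seen is tracked and returned.
## multi_start_search: 500 random 6-sample starts, two warm AR-Cstep
##                    iterations each, keep the 10 best, run those to
##                    convergence.
## exhaustive_oracle : fits every stratified size-h subset (test oracle).

#' Concentration step at fixed regularization
#'
#' Iterates fit -> rank deviances -> re-form the subset from the `h`
#' best-fitting observations, until the subset or the criterion stops
#' changing. With `lambda` and `alpha` fixed and a fixed standardization the
#' criterion sequence is non-increasing and the iteration converges in
#' finitely many steps.
#'
#' @param data A [labeled_matrix()].
#' @param H0 Initial index set; may be smaller than `plan$h` (e.g. a 6-sample
#'   seed subset), in which case the first candidate expands it to size `h`.
#' @param lam,alpha Fixed regularization parameters.
#' @param plan A [make_plan()].
#' @param tol Stop when the criterion changes by less than this (default
#'   1e-6).
#' @param max_iter Iteration cap (default 100); hitting it is flagged in the
#'   trace attributes, not silent.
#' @param stratified Use the class-stratified candidate rule (default `TRUE`);
#'   `FALSE` gives the plain h-smallest rule of the classic C-step baseline.
#' @param standardization Optional fixed standardization (list of `means`,
#'   `sds`); default: full-data statistics, computed once.
#' @return List with `state` (a [subset_state()]) and `trace`, a data.frame
#'   with one row per iteration (columns `iter`, `size`, `Q`,
#'   `Q_cand_under_cur`) and attributes `converged`, `iterations`,
#'   `fit_count`.
#' @export
cstep_fixed <- function(data, H0, lam, alpha, plan, tol = 1e-6,
                        max_iter = 100, stratified = TRUE,
                        standardization = NULL) {
  assert_labeled_matrix(data)
  if (is.null(standardization)) {
    sb <- standardize_by_subset(data, seq_len(data$n))
    std <- sb$std
    x_std <- sb$x
  } else {
    std <- standardization
    x_std <- apply_standardization(data$X, std)
  }
  H <- sort(as.integer(H0))
  fc0 <- get_fit_count()
  rows <- vector("list", max_iter)
  Q_prev <- Inf
  model <- NULL
  converged <- FALSE
  perturbed <- FALSE
  for (m in seq_len(max_iter)) {
    model <- tryCatch(
      fit_penalized_logistic(data, H, lam, alpha, standardization = std,
                             x_std = x_std),
      error = function(e) e
    )
    if (inherits(model, "error")) {
      if (!perturbed && grepl("degenerate subset", conditionMessage(model))) {
        # one perturbed restart: a random stratified subset of size h
        perturbed <- TRUE
        H <- sort(c(sample(which(data$y == 1L), plan$h1),
                    sample(which(data$y == 0L), plan$h0)))
        next
      }
      stop2("cstep_fixed failed at iteration ", m, ": ",
            conditionMessage(model))
    }
    Q_fit <- trim_criterion(H, model)
    H_next <- select_candidate_subset(model$deviances_full, data$y, plan,
                                      stratified = stratified)
    rows[[m]] <- data.frame(iter = m, size = length(H), Q = Q_fit,
                            Q_cand_under_cur = trim_criterion(H_next, model))
    if (identical(H_next, H) ||
        (length(H) == plan$h && abs(Q_fit - Q_prev) < tol)) {
      converged <- TRUE
      break
    }
    if (length(H) == plan$h) Q_prev <- Q_fit
    H <- H_next
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(trace, "converged") <- converged
  attr(trace, "iterations") <- nrow(trace)
  attr(trace, "fit_count") <- get_fit_count() - fc0
  list(state = subset_state(H, model), trace = trace)
}

#' Grid-search concentration step (the expensive baseline)
#'
#' Runs [cstep_fixed()] to convergence for every (lambda, alpha) combination
#' of the grid and every start, and returns the converged state with the
#' smallest criterion. With 40 lambda and 20 alpha values this is 800 C-step
#' runs per start — the cost that motivates the acceptance-rejection variant.
#'
#' @param data A [labeled_matrix()].
#' @param starts List of initial index sets.
#' @param grid A [reg_grid()].
#' @param plan A [make_plan()].
#' @param ... Passed to [cstep_fixed()] (`tol`, `max_iter`, `stratified`).
#' @return The best [subset_state()], with attributes `run_count` (number of
#'   cstep_fixed invocations) and `fit_count` (total penalized fits).
#' @export
cstep_grid <- function(data, starts, grid, plan, ...) {
  assert_labeled_matrix(data)
  if (!is.list(starts)) starts <- list(starts)
  std <- standardize_by_subset(data, seq_len(data$n))$std
  fc0 <- get_fit_count()
  runs <- 0L
  best <- NULL
  for (alpha in grid$alphas) {
    for (lam in grid_lambdas(grid)) {
      for (H0 in starts) {
        res <- cstep_fixed(data, H0, lam, alpha, plan,
                           standardization = std, ...)
        runs <- runs + 1L
        if (is.null(best) || res$state$Q < best$Q) best <- res$state
      }
    }
  }
  attr(best, "run_count") <- runs
  attr(best, "fit_count") <- get_fit_count() - fc0
  best
}

#' Metropolis-type acceptance probability for a worse candidate subset
#'
#' \eqn{p = \exp\{\tau_k (\log\ell_{cand} - \log\ell_{cur})\}} with
#' \eqn{\tau_k = \log(k + 1) / D}: at iteration `k = 0` every candidate is
#' accepted (`p = 1`); as `k` grows, or as the candidate's log-likelihood
#' falls further below the current one, acceptance becomes less likely. `D =
#' 0.1 n (1 - eta)` scales the schedule with the number of trimmed samples.
#'
#' @param loglik_cand,loglik_cur Unpenalized subset log-likelihoods of the
#'   candidate and current fits (the candidate is the worse one).
#' @param k Iteration counter, `k >= 0`.
#' @param D Positive temperature scale.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' acceptance_probability(-11, -10, k = 9, D = 2.5) # ~0.398
acceptance_probability <- function(loglik_cand, loglik_cur, k, D) {
  if (!is.finite(D) || D <= 0) stop2("D must be > 0")
  if (k < 0) stop2("k must be >= 0")
  tau <- log(k + 1) / D
  min(1, exp(tau * (loglik_cand - loglik_cur)))
}

#' AR-Cstep configuration
#'
#' @param n_starts Number of random 6-sample initial subsets (default 500).
#' @param warm_steps AR-Cstep iterations per start in the warm phase
#'   (default 2).
#' @param keep Number of warm-started states retained for full convergence
#'   (default 10); must not exceed `n_starts`.
#' @param stall_limit Stop a run after this many consecutive iterations
#'   without the current subset being replaced (default 3).
#' @param max_iter Iteration cap per run (default 100).
#' @param tol Criterion change below which a replacement does not count as
#'   progress (default 1e-6).
#' @param seed Integer seed; every random draw of a search (initial subsets,
#'   cross-validation folds, Bernoulli accept draws) flows from it.
#' @param folds Cross-validation folds for the per-iteration lambda selection
#'   (default 5).
#' @return Object of class `ar_cstep_config`.
#' @export
ar_cstep_config <- function(n_starts = 500, warm_steps = 2, keep = 10,
                            stall_limit = 3, max_iter = 100, tol = 1e-6,
                            seed = 1, folds = 5) {
  if (keep > n_starts) stop2("keep must be <= n_starts")
  if (stall_limit < 1) stop2("stall_limit must be >= 1")
  structure(list(n_starts = as.integer(n_starts),
                 warm_steps = as.integer(warm_steps),
                 keep = as.integer(keep),
                 stall_limit = as.integer(stall_limit),
                 max_iter = as.integer(max_iter),
                 tol = tol, seed = seed, folds = as.integer(folds)),
            class = "ar_cstep_config")
}

## Fit a subset inside an AR-Cstep run. Adaptive mode: lambda by stratified
## CV on the subset (alpha comes with it from the grid); subsets too small
## for CV (the 6-sample warm starts) use the largest grid lambda instead --
## heavy shrinkage -- which is logged in the trace via lambda_rule.
ar_fit_state <- function(data, H, plan, grid, cfg, lam, alpha, std_fixed) {
  H <- sort(as.integer(H))
  if (!is.null(lam)) {
    model <- fit_penalized_logistic(data, H, lam, alpha,
                                    standardization = std_fixed)
    rule <- "fixed"
  } else {
    ys <- data$y[H]
    if (length(H) < plan$h || min(sum(ys == 1L), sum(ys == 0L)) < 2L) {
      # subset too small for cross-validation (the 6-sample warm starts):
      # use the largest grid lambda that yields a non-degenerate fit, i.e.
      # the heaviest shrinkage under which at least one feature enters
      model <- fit_heaviest_nondegenerate(data, H, grid)
      rule <- "max_shrinkage"
    } else {
      sel <- cv_select(data, H, grid, folds = cfg$folds, seed = NULL)
      model <- fit_penalized_logistic(data, H, sel$lam, sel$alpha)
      rule <- "cv"
    }
  }
  list(H = H, model = model,
       Q = trim_criterion(H, model),
       ll = model$loglik_subset,
       rule = rule)
}

## Largest grid lambda whose fit on H has at least one nonzero slope: one
## path call over the iteration grid, then the model is rebuilt at the
## winning lambda.
fit_heaviest_nondegenerate <- function(data, H, grid) {
  sb <- standardize_by_subset(data, H)
  lambdas_dec <- rev(grid_lambdas(grid))
  fit <- fit_en_path(sb$x[H, , drop = FALSE], data$y[H], lambdas_dec,
                     grid$alphas[1])
  nz <- colSums(as.matrix(fit$beta) != 0)
  j <- which(nz > 0)[1]
  if (is.na(j)) j <- length(lambdas_dec) # fully degenerate: least shrinkage
  beta <- as.numeric(fit$beta[, j])
  intercept <- as.numeric(fit$a0[j])
  eta_all <- as.numeric(intercept + sb$x %*% beta)
  dev <- bernoulli_deviance(data$y, stats::plogis(eta_all))
  structure(
    list(intercept = intercept, beta = beta,
         beta_original = beta / sb$std$sds,
         intercept_original = intercept - sum(beta * sb$std$means / sb$std$sds),
         lam = lambdas_dec[j], alpha = grid$alphas[1],
         standardization = sb$std, subset = sort(as.integer(H)),
         deviances_full = dev, loglik_subset = -sum(dev[H]),
         feature_ids = data$feature_ids),
    class = "penalized_model"
  )
}

#' One AR-Cstep run
#'
#' Starting from `H0`, each iteration `k` builds the stratified candidate
#' subset from the current model's full-data deviances and fits it at the
#' current subset's regularization; a newly accepted subset is then refit
#' with its own cross-validated lambda when it becomes current (one lambda
#' selection per iteration, on the current subset — see the methods
#' vignette for why the candidate is not allowed to bring its own lambda
#' into the comparison). A candidate that does not worsen the criterion is
#' accepted outright; a worse one is accepted with probability
#' [acceptance_probability()] via a Bernoulli draw, so the search can
#' escape local optima. The best size-h
#' state ever visited (`H_opt`) is tracked and returned — not the last one.
#' The run stops after `stall_limit` consecutive iterations without progress,
#' or at `max_iter`.
#'
#' Randomness (fold splits, Bernoulli draws) is consumed from the current RNG
#' stream; seed it with [with_seed] semantics via the caller (see
#' [multi_start_search()]) for bit-reproducible runs.
#'
#' @param data A [labeled_matrix()].
#' @param H0 Initial index set (size `plan$h`, or smaller for a warm start).
#' @param plan A [make_plan()].
#' @param grid Iteration-phase [reg_grid()] (alpha = 0.5).
#' @param cfg An [ar_cstep_config()].
#' @param lam,alpha Optional fixed regularization; when supplied the run uses
#'   a fixed full-data standardization and no cross-validation (useful for
#'   oracle comparisons; with fixed parameters the candidate never worsens
#'   the criterion and the run reduces to a concentration step).
#' @param max_iter Override of `cfg$max_iter` (used for the warm phase).
#' @return List with `state` (best [subset_state()]), and `trace`: one row
#'   per iteration (`k`, `Q_before`, `Q_cand`, `Q_cur`, `p_accept`,
#'   `accepted`, `replaced`, `Q_opt`, `lam_cur`, `rule_cur`) with attributes
#'   `stopped` (`"stalled"`, `"max_iter"`), `fit_count`.
#' @export
ar_cstep_run <- function(data, H0, plan, grid, cfg = ar_cstep_config(),
                         lam = NULL, alpha = NULL, max_iter = cfg$max_iter) {
  assert_labeled_matrix(data)
  if (plan$h1 > plan$n1 || plan$h0 > plan$n0) stop2("infeasible plan")
  if (!is.null(lam) && is.null(alpha)) alpha <- grid$alphas[1]
  std_fixed <- if (is.null(lam)) NULL else
    standardize_by_subset(data, seq_len(data$n))$std
  D <- 0.1 * plan$n * (1 - plan$eta)
  fc0 <- get_fit_count()

  cur <- ar_fit_state(data, H0, plan, grid, cfg, lam, alpha, std_fixed)
  full_size <- length(cur$H) == plan$h
  opt <- if (full_size) cur else NULL
  Q_opt <- if (full_size) cur$Q else Inf

  stall <- 0L
  stopped <- "max_iter"
  rows <- vector("list", max_iter)
  for (k in seq_len(max_iter) - 1L) {
    cand_idx <- select_candidate_subset(cur$model$deviances_full, data$y,
                                        plan, stratified = TRUE)
    # one lambda selection per iteration, on the current subset: the
    # candidate is fitted and compared at the current parameters, so a
    # candidate can never win merely by bringing along a more
    # self-indulgent regularization choice
    cand <- ar_fit_state(data, cand_idx, plan, grid, cfg,
                         lam %||% cur$model$lam,
                         alpha %||% cur$model$alpha, std_fixed)
    Q_before <- cur$Q
    worse <- cand$Q > Q_before
    if (worse) {
      p <- acceptance_probability(cand$ll, cur$ll, k, D)
      accepted <- stats::rbinom(1L, 1L, p) == 1L
    } else {
      p <- 1
      accepted <- TRUE
    }
    replaced <- accepted && !identical(cand$H, cur$H)
    progress <- replaced && abs(cand$Q - cur$Q) > cfg$tol
    if (replaced) {
      # the accepted subset becomes current and gets its own
      # cross-validated regularization (the lambda_2 of the next
      # comparison); in fixed-parameter mode this refit is a no-op
      cur <- if (is.null(lam)) {
        ar_fit_state(data, cand$H, plan, grid, cfg, NULL, NULL, std_fixed)
      } else {
        cand
      }
    } else if (accepted) {
      cur <- cand
    }
    if (length(cur$H) == plan$h && cur$Q < Q_opt) {
      Q_opt <- cur$Q
      opt <- cur
    }
    rows[[k + 1L]] <- data.frame(
      k = k, Q_before = Q_before, Q_cand = cand$Q, Q_cur = cur$Q,
      p_accept = p, accepted = accepted, replaced = replaced, Q_opt = Q_opt,
      lam_cur = cur$model$lam, rule_cur = cur$rule
    )
    stall <- if (progress) 0L else stall + 1L
    if (stall >= cfg$stall_limit) {
      stopped <- "stalled"
      break
    }
  }
  trace <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(trace, "stopped") <- stopped
  attr(trace, "fit_count") <- get_fit_count() - fc0
  if (is.null(opt)) stop2("no size-h state was visited; increase max_iter")
  list(state = subset_state(opt$H, opt$model, plan), trace = trace)
}

#' Multi-start AR-Cstep search
#'
#' Draws `cfg$n_starts` initial subsets of six observations (three per
#' class, sampled without replacement), runs `cfg$warm_steps` AR-Cstep
#' iterations on each, retains the `cfg$keep` states with the smallest
#' criterion, runs each retained state to convergence, and returns the
#' converged state with minimal criterion. The whole search is reproducible
#' from `cfg$seed`.
#'
#' @param data A [labeled_matrix()] with at least 3 samples per class.
#' @param plan A [make_plan()].
#' @param grid Iteration-phase [reg_grid()].
#' @param cfg An [ar_cstep_config()].
#' @return The best [subset_state()], with attributes `fit_count`, `warm_Q`
#'   (criterion of every warm-started state) and `kept_Q` (criterion of each
#'   retained state after full convergence).
#' @export
multi_start_search <- function(data, plan, grid, cfg = ar_cstep_config()) {
  assert_labeled_matrix(data)
  if (data$n1 < 3L || data$n0 < 3L) stop2("too few samples per class (need >= 3)")
  i1 <- which(data$y == 1L)
  i0 <- which(data$y == 0L)
  fc0 <- get_fit_count()
  with_seed(cfg$seed, {
    warm <- vector("list", cfg$n_starts)
    for (s in seq_len(cfg$n_starts)) {
      H0 <- sort(c(sample(i1, 3L), sample(i0, 3L)))
      warm[[s]] <- ar_cstep_run(data, H0, plan, grid, cfg,
                                max_iter = cfg$warm_steps)$state
    }
    warm_Q <- vapply(warm, function(s) s$Q, numeric(1))
    retained <- warm[order(warm_Q)[seq_len(cfg$keep)]]
    best <- NULL
    kept_Q <- numeric(cfg$keep)
    for (j in seq_len(cfg$keep)) {
      res <- ar_cstep_run(data, retained[[j]]$H, plan, grid, cfg)
      kept_Q[j] <- res$state$Q
      if (is.null(best) || res$state$Q < best$Q) best <- res$state
    }
    attr(best, "fit_count") <- get_fit_count() - fc0
    attr(best, "warm_Q") <- warm_Q
    attr(best, "kept_Q") <- kept_Q
    best
  })
}

#' Exhaustive stratified-subset oracle
#'
#' Fits every size-h subset honoring the (h1, h0) class split at fixed
#' (lambda, alpha) with a fixed full-data standardization, and returns the
#' global minimum-criterion state. A test oracle: guarded to small problems.
#'
#' @param data A [labeled_matrix()].
#' @param plan A [make_plan()].
#' @param lam,alpha Fixed regularization.
#' @param guard Maximum number of subsets (default 1e5).
#' @return The globally optimal [subset_state()], with attribute
#'   `n_subsets` = choose(n1, h1) * choose(n0, h0).
#' @export
exhaustive_oracle <- function(data, plan, lam, alpha, guard = 1e5) {
  assert_labeled_matrix(data)
  n_subsets <- choose(data$n1, plan$h1) * choose(data$n0, plan$h0)
  if (n_subsets > guard) {
    stop2("combinatorial guard exceeded: ", format(n_subsets, big.mark = ","),
          " stratified subsets > ", guard)
  }
  sb <- standardize_by_subset(data, seq_len(data$n))
  i1 <- which(data$y == 1L)
  i0 <- which(data$y == 0L)
  sets1 <- utils::combn(i1, plan$h1)
  sets0 <- utils::combn(i0, plan$h0)
  best <- NULL
  for (a in seq_len(ncol(sets1))) {
    for (b in seq_len(ncol(sets0))) {
      H <- sort(c(sets1[, a], sets0[, b]))
      model <- fit_penalized_logistic(data, H, lam, alpha,
                                      standardization = sb$std,
                                      x_std = sb$x)
      Q <- trim_criterion(H, model)
      if (is.null(best) || Q < best$Q) best <- subset_state(H, model, plan)
    }
  }
  attr(best, "n_subsets") <- n_subsets
  best
}

#' Export a search trace as JSON lines
#'
#' One JSON object per iteration record, suitable for debugging and for the
#' hardware-free cost accounting.
#'
#' @param trace A trace data.frame from [cstep_fixed()] or [ar_cstep_run()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace))) {
    writeLines(jsonlite::toJSON(as.list(trace[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
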