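## Core model: subset-standardized elastic-net penalized logistic regression.
##
## The fitted objective on a subset H of size m is
##   sum_{i in H} d(y_i, b0 + x_i'beta) + m * lambda * P_alpha(beta),
##   P_alpha(beta) = sum_j [ (1 - alpha) beta_j^2 / 2 + alpha |beta_j| ],
## with an unpenalized intercept and d() the Bernoulli negative log-likelihood
## contribution ("deviance", no factor 2 -- orderings are invariant to it).
## Dividing by m shows this is exactly the glmnet binomial objective at the
## same lambda, so glmnet (coordinate descent) is the inner solver.

#' Elastic-net penalty value
#'
#' \eqn{P_\alpha(\beta) = \sum_j [(1-\alpha)\beta_j^2/2 + \alpha|\beta_j|]}.
#'
#' @param beta Numeric vector of slopes (standardized scale).
#' @param alpha Elastic-net mixing parameter in (0, 1]; 1 is the lasso.
#' @return Scalar penalty value.
#' @export
en_penalty <- function(beta, alpha) {
  sum((1 - alpha) * beta^2 / 2 + alpha * abs(beta))
}

#' Largest useful regularization strength
#'
#' Computes \eqn{\lambda_{max} = \max_j n^{-1} |X_j' y|} on the (by default
#' unit-scaled) full data. Regularization grids are fractions of this value.
#' The formula is the classical Gaussian-lasso entry point; for the logistic
#' family the coefficient path is not guaranteed to vanish exactly at this
#' value, but the grids only need a common, data-driven scale.
#'
#' @param data A [labeled_matrix()].
#' @param standardize Scale each column to zero mean / unit sd (computed on
#'   all rows) before taking the inner product. Default `TRUE`.
#' @return Positive scalar.
#' @export
compute_lambda_max <- function(data, standardize = TRUE) {
  assert_labeled_matrix(data)
  y <- data$y
  if (length(unique(y)) < 2L) stop2("degenerate labels: y is constant")
  X <- data$X
  if (standardize) {
    X <- standardize_by_subset(data, seq_len(data$n))$x
  }
  max(abs(crossprod(X, y))) / data$n
}

#' Standardize all rows using subset-derived column statistics
#'
#' Column means and standard deviations are computed on the subset rows only
#' (the robust convention: the fitting subset should not be contaminated),
#' then *all* n rows are transformed as `(x - mean) / sd`. Columns that are
#' constant on the subset get their sd replaced by 1, so the transform stays
#' defined.
#'
#' @param data A [labeled_matrix()].
#' @param subset Integer indices (1-based) of the rows defining the statistics.
#' @return List with `x` (transformed n x p matrix) and `std`, a list holding
#'   `means` and `sds` (each length p, every sd > 0).
#' @export
standardize_by_subset <- function(data, subset) {
  assert_labeled_matrix(data)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop2("subset must be non-empty")
  if (any(subset < 1L | subset > data$n)) stop2("subset indices out of range")
  Xs <- data$X[subset, , drop = FALSE]
  m <- nrow(Xs)
  means <- colMeans(Xs)
  sds <- if (m > 1L) {
    sqrt(pmax(colSums(Xs * Xs) - m * means^2, 0) / (m - 1))
  } else {
    rep(0, data$p)
  }
  sds[!is.finite(sds) | sds == 0] <- 1
  x <- apply_standardization(data$X, list(means = means, sds = sds))
  list(x = x, std = list(means = means, sds = sds))
}

## Centered/scaled copy of a matrix under given column statistics; the
## transpose trick beats two sweep() passes on wide matrices.
apply_standardization <- function(X, std) {
  t((t(X) - std$means) / std$sds)
}

## One call into the coordinate-descent solver. `lambdas` must be decreasing.
## Counts as a single penalized fit for cost accounting: with warm starts a
## whole path costs about as much as one cold fit.
fit_en_path <- function(x, y, lambdas, alpha, thresh = 1e-8, maxit = 1e5) {
  .mtlen_state$fit_count <- .mtlen_state$fit_count + 1L
  fit <- suppressWarnings(glmnet::glmnet(
    x, factor(y, levels = c(0, 1)), family = "binomial", alpha = alpha,
    lambda = lambdas, standardize = FALSE, intercept = TRUE,
    thresh = thresh, maxit = maxit
  ))
  if (length(fit$lambda) != length(lambdas)) {
    stop2("inner solver returned ", length(fit$lambda), " of ",
          length(lambdas), " requested lambda values (after ",
          fit$npasses, " passes)")
  }
  fit
}

## Pad a single target lambda with a short decreasing warm-start path.
lambda_path_for <- function(lam) {
  anchor <- max(lam, 1e-4)
  sort(unique(c(anchor * c(32, 16, 8, 4, 2), lam)), decreasing = TRUE)
}

#' Fit a penalized logistic regression on a subset
#'
#' Fits the elastic-net penalized logistic model on the rows in `subset`,
#' standardized by subset-derived statistics (or by an explicitly supplied
#' standardization), and evaluates per-observation deviances on *all* n rows.
#'
#' @param data A [labeled_matrix()].
#' @param subset Integer row indices to fit on; must contain both classes.
#' @param lam Regularization strength \eqn{\lambda \ge 0}.
#' @param alpha Elastic-net mixing in (0, 1].
#' @param standardization Optional list (`means`, `sds`) to use instead of
#'   subset-derived statistics. Fixing the standardization across subsets
#'   makes criterion values exactly comparable (used by the fixed-parameter
#'   C-step and the exhaustive oracle).
#' @param x_std Optional pre-standardized n x p matrix matching
#'   `standardization` (a cache for hot loops that refit many subsets under
#'   one fixed standardization).
#' @param thresh,maxit Inner solver tolerance and pass limit.
#' @return An object of class `penalized_model`: intercept and slopes on the
#'   standardized scale, `beta_original`/`intercept_original` on the input
#'   scale, `lam`, `alpha`, the standardization, `deviances_full` (length n,
#'   all >= 0) and `loglik_subset` (= minus the subset deviance sum).
#' @export
fit_penalized_logistic <- function(data, subset, lam, alpha,
                                   standardization = NULL, x_std = NULL,
                                   thresh = 1e-8, maxit = 1e5) {
  assert_labeled_matrix(data)
  subset <- sort(as.integer(subset))
  if (lam < 0) stop2("lam must be >= 0")
  if (alpha <= 0 || alpha > 1) stop2("alpha must be in (0, 1]")
  ys <- data$y[subset]
  if (length(unique(ys)) < 2L) stop2("degenerate subset: only one class present")
  if (is.null(standardization)) {
    sb <- standardize_by_subset(data, subset)
  } else if (!is.null(x_std)) {
    sb <- list(x = x_std, std = standardization)
  } else {
    sb <- list(x = apply_standardization(data$X, standardization),
               std = standardization)
  }
  path <- lambda_path_for(lam)
  fit <- fit_en_path(sb$x[subset, , drop = FALSE], ys, path, alpha,
                     thresh = thresh, maxit = maxit)
  j <- which.min(abs(fit$lambda - lam))
  beta <- as.numeric(fit$beta[, j])
  intercept <- as.numeric(fit$a0[j])
  eta_all <- as.numeric(intercept + sb$x %*% beta)
  prob <- clip_prob(stats::plogis(eta_all))
  dev <- bernoulli_deviance(data$y, prob)
  structure(
    list(
      intercept = intercept,
      beta = beta,
      beta_original = beta / sb$std$sds,
      intercept_original = intercept - sum(beta * sb$std$means / sb$std$sds),
      lam = lam,
      alpha = alpha,
      standardization = sb$std,
      subset = subset,
      deviances_full = dev,
      loglik_subset = -sum(dev[subset]),
      feature_ids = data$feature_ids
    ),
    class = "penalized_model"
  )
}

#' @export
print.penalized_model <- function(x, ...) {
  cat("<penalized_model> lambda = ", signif(x$lam, 4), ", alpha = ", x$alpha,
      "; ", sum(x$beta != 0), " nonzero slopes of ", length(x$beta),
      "; fitted on ", length(x$subset), " samples\n", sep = "")
  invisible(x)
}

#' Fitted class-1 probabilities
#'
#' @param model A `penalized_model`.
#' @param data A [labeled_matrix()] with the same features.
#' @param clip Clip probabilities away from 0/1 (default `TRUE`).
#' @return Numeric vector of length n.
#' @export
predicted_prob <- function(model, data, clip = TRUE) {
  assert_labeled_matrix(data)
  eta <- model$intercept_original + as.numeric(data$X %*% model$beta_original)
  p <- stats::plogis(eta)
  if (clip) clip_prob(p) else p
}

#' Per-observation deviances under a fitted model
#'
#' \eqn{d_i = -[y_i \log \pi_i + (1-y_i)\log(1-\pi_i)]} with probabilities
#' clipped to `[1e-10, 1 - 1e-10]`; always finite and nonnegative. The
#' ordering of these values defines subset membership in the trimming
#' algorithms.
#'
#' @inheritParams predicted_prob
#' @return Numeric vector of length n.
#' @export
per_observation_deviance <- function(model, data) {
  bernoulli_deviance(data$y, predicted_prob(model, data))
}

#' Regularization grid
#'
#' A grid is a set of fractions of a common `lambda_max` plus a set of
#' elastic-net mixing values. Two phases are predefined: the cheap
#' *iteration* grid used inside the AR-Cstep search (20 lambda fractions
#' 0.05, 0.10, ..., 1.00 at alpha = 0.5) and the fine *refit* grid used for
#' the final estimates (100 fractions 0.01, ..., 1.00 crossed with alpha =
#' 0.1, 0.2, ..., 1.0).
#'
#' @param lambda_max Positive scalar, see [compute_lambda_max()].
#' @param phase `"iteration"` or `"refit"`.
#' @return An object of class `reg_grid` with `lambda_max`,
#'   `lambda_fractions` (strictly increasing, ending at 1) and `alphas`.
#' @export
build_grids <- function(lambda_max, phase = c("iteration", "refit")) {
  phase <- match.arg(phase)
  if (!is.finite(lambda_max) || lambda_max <= 0) stop2("lambda_max must be > 0")
  if (phase == "iteration") {
    reg_grid(lambda_max, seq(0.05, 1, by = 0.05), 0.5)
  } else {
    reg_grid(lambda_max, seq(0.01, 1, by = 0.01), seq(0.1, 1, by = 0.1))
  }
}

#' @rdname build_grids
#' @param lambda_fractions Strictly increasing vector in (0, 1], last value 1.
#' @param alphas Non-empty vector in (0, 1].
#' @export
reg_grid <- function(lambda_max, lambda_fractions, alphas) {
  lambda_fractions <- as.numeric(lambda_fractions)
  alphas <- as.numeric(alphas)
  if (length(lambda_fractions) == 0L || any(diff(lambda_fractions) <= 0)) {
    stop2("lambda_fractions must be strictly increasing")
  }
  if (any(lambda_fractions <= 0) || abs(lambda_fractions[length(lambda_fractions)] - 1) > 1e-12) {
    stop2("lambda_fractions must lie in (0, 1] and end at 1")
  }
  if (length(alphas) == 0L || any(alphas <= 0 | alphas > 1)) {
    stop2("alphas must be non-empty, in (0, 1]")
  }
  structure(list(lambda_max = lambda_max,
                 lambda_fractions = lambda_fractions,
                 alphas = alphas),
            class = "reg_grid")
}

#' @export
print.reg_grid <- function(x, ...) {
  cat("<reg_grid> ", length(x$lambda_fractions), " lambda fractions x ",
      length(x$alphas), " alphas; lambda_max = ", signif(x$lambda_max, 4),
      "\n", sep = "")
  invisible(x)
}

grid_lambdas <- function(grid) grid$lambda_fractions * grid$lambda_max

## Stratified fold assignment for rows with labels y01; deterministic under
## the current RNG state.
stratified_folds <- function(y01, folds) {
  fold_id <- integer(length(y01))
  for (cls in c(1L, 0L)) {
    idx <- which(y01 == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

#' Cross-validated selection of (lambda, alpha) on a subset
#'
#' Stratified k-fold cross-validation restricted to `subset`. For each fold
#' and each alpha one warm-started path fit covers the whole lambda grid;
#' the loss is the mean held-out deviance. Ties are broken deterministically
#' (first minimum in alpha-ascending, lambda-descending order). Each training
#' split is standardized by its own rows.
#'
#' @param data A [labeled_matrix()].
#' @param subset Row indices to cross-validate within.
#' @param grid A [reg_grid()].
#' @param folds Number of folds (default 5). If a class has fewer members
#'   than `folds`, the fold count is reduced (minimum 2) with a warning.
#' @param seed Optional seed; the same seed always yields the same folds and
#'   hence the same selection. `NULL` consumes the current RNG stream.
#' @return List with `lam`, `alpha`, `folds` (folds actually used), and
#'   `cvm` (mean held-out deviance, lambda-descending x alpha matrix).
#' @export
cv_select <- function(data, subset, grid, folds = 5, seed = NULL) {
  assert_labeled_matrix(data)
  subset <- sort(as.integer(subset))
  ys <- data$y[subset]
  n1s <- sum(ys == 1L); n0s <- sum(ys == 0L)
  if (n1s < 2L || n0s < 2L) {
    stop2("subset too small for cross-validation: need >= 2 rows per class")
  }
  folds_eff <- max(2L, min(as.integer(folds), n1s, n0s))
  if (folds_eff < folds) {
    warning("cv_select: reducing folds from ", folds, " to ", folds_eff,
            " (small subset)", call. = FALSE)
  }
  lambdas_dec <- rev(grid_lambdas(grid))
  nl <- length(lambdas_dec)
  na <- length(grid$alphas)
  with_seed(seed, {
    fold_id <- stratified_folds(ys, folds_eff)
    dev_sum <- matrix(0, nl, na)
    for (a in seq_len(na)) {
      for (f in seq_len(folds_eff)) {
        train <- subset[fold_id != f]
        test <- subset[fold_id == f]
        # train-row statistics; only the rows in play are transformed
        Xt <- data$X[train, , drop = FALSE]
        mu <- colMeans(Xt)
        sg <- sqrt(pmax(colSums(Xt * Xt) - nrow(Xt) * mu^2, 0) / (nrow(Xt) - 1))
        sg[!is.finite(sg) | sg == 0] <- 1
        std_f <- list(means = mu, sds = sg)
        fit <- fit_en_path(apply_standardization(Xt, std_f), data$y[train],
                           lambdas_dec, grid$alphas[a])
        x_test <- apply_standardization(data$X[test, , drop = FALSE], std_f)
        eta <- cbind(1, x_test) %*%
          rbind(as.numeric(fit$a0), as.matrix(fit$beta))
        prob <- clip_prob(stats::plogis(eta))
        dv <- -(data$y[test] * log(prob) + (1 - data$y[test]) * log(1 - prob))
        dev_sum[, a] <- dev_sum[, a] + colSums(dv)
      }
    }
    cvm <- dev_sum / length(subset)
    best <- arrayInd(which.min(cvm), dim(cvm))
    list(lam = lambdas_dec[best[1]], alpha = grid$alphas[best[2]],
         folds = folds_eff, cvm = cvm)
  })
}
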