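## Reweighted step: refit on the optimal trimmed subset with fine grids,
## flag outliers by Pearson residual, refit on the cleaned subset.

#' Refit on a subset with the fine regularization grid
#'
#' Cross-validates (lambda, alpha) over the refit grid (by default 100
#' lambda fractions x 10 alphas) restricted to `H`, then fits the winner on
#' `H` with subset standardization. Used for both the raw estimate (on the
#' optimal trimmed subset) and the reweighted estimate (on the cleaned
#' subset).
#'
#' @param data A [labeled_matrix()].
#' @param H Index set containing both classes.
#' @param grid A refit-phase [reg_grid()]; default built from the data.
#' @param folds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A `penalized_model`.
#' @export
refit_on_subset <- function(data, H, grid = NULL, folds = 5, seed = NULL) {
  assert_labeled_matrix(data)
  grid <- grid %||% build_grids(compute_lambda_max(data), "refit")
  sel <- cv_select(data, H, grid, folds = folds, seed = seed)
  fit_penalized_logistic(data, H, sel$lam, sel$alpha)
}

#' Pearson residuals of a fitted model
#'
#' \eqn{r_i = (y_i - \hat\pi_i) / \sqrt{\hat\pi_i (1 - \hat\pi_i)}} with
#' probabilities clipped as everywhere else. Mislabeled samples sit far from
#' their fitted probability and get large `|r|`.
#'
#' @param model A `penalized_model`.
#' @param data A [labeled_matrix()].
#' @return Numeric vector of length n.
#' @export
pearson_residuals <- function(model, data) {
  p <- predicted_prob(model, data)
  (data$y - p) / sqrt(p * (1 - p))
}

#' Flag outliers by absolute Pearson residual
#'
#' @param residuals Numeric vector of Pearson residuals.
#' @param cutoff Positive threshold `c`; samples with `|r| > c` are flagged.
#'   Default 2.5, the classical reweighting convention in the trimmed-
#'   estimation literature.
#' @param sample_ids Optional identifiers, reported for flagged samples.
#' @return Object of class `outlier_report`: `pearson_residuals`, `cutoff`,
#'   `flags` (logical), `flagged` (integer indices), `flagged_ids`,
#'   `H_rwt` (indices of unflagged samples).
#' @export
detect_outliers <- function(residuals, cutoff = 2.5, sample_ids = NULL) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop2("cutoff must be > 0")
  flags <- abs(residuals) > cutoff
  flagged <- which(flags)
  structure(
    list(pearson_residuals = residuals, cutoff = cutoff, flags = flags,
         flagged = flagged,
         flagged_ids = if (is.null(sample_ids)) as.character(flagged)
                       else sample_ids[flagged],
         H_rwt = which(!flags)),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", length(x$flagged), " of ", length(x$flags),
      " samples flagged at |Pearson residual| > ", x$cutoff, "\n", sep = "")
  invisible(x)
}

#' Robust trimmed elastic-net logistic regression with outlier detection
#'
#' The full MTL-EN pipeline: (1) multi-start AR-Cstep search for the optimal
#' trimmed subset `H_opt` of size `h = floor(n * eta)`; (2) refit on `H_opt`
#' over the fine grid — the *raw* estimate; (3) Pearson residuals of the raw
#' fit on all n samples; samples with `|r| > cutoff` are flagged as
#' mislabeled; (4) refit on the unflagged samples `H_rwt` (usually larger
#' than `h`) — the *reweighted* estimate, used for variable selection.
#'
#' @param data A [labeled_matrix()].
#' @param eta Retained fraction in (0.5, 1] (default 0.75: up to 25%
#'   contamination is tolerated during the search).
#' @param cutoff Pearson-residual cutoff for outlier flagging (default 2.5).
#' @param cfg An [ar_cstep_config()]; `cfg$seed` drives every random draw of
#'   the whole pipeline.
#' @param folds Cross-validation folds for the two refits (default 5).
#' @return Object of class `robust_fit`: `raw_model`, `H_opt`, `rwt_model`,
#'   `H_rwt`, `report` (an `outlier_report`), `plan`, `search` (the best
#'   search state with its attributes), `seeds` (the derived refit seeds),
#'   `data_dim`.
#' @export
mtl_en <- function(data, eta = 0.75, cutoff = 2.5, cfg = ar_cstep_config(),
                   folds = 5) {
  assert_labeled_matrix(data)
  plan <- plan_for_data(data, eta)
  lambda_max <- compute_lambda_max(data)
  iter_grid <- build_grids(lambda_max, "iteration")
  refit_grid <- build_grids(lambda_max, "refit")

  search <- multi_start_search(data, plan, iter_grid, cfg)
  H_opt <- search$H

  raw_seed <- derive_seed(cfg$seed, 1L)
  rwt_seed <- derive_seed(cfg$seed, 2L)
  raw_model <- refit_on_subset(data, H_opt, refit_grid, folds, raw_seed)
  resid <- pearson_residuals(raw_model, data)
  report <- detect_outliers(resid, cutoff, data$sample_ids)
  rwt_model <- refit_on_subset(data, report$H_rwt, refit_grid, folds, rwt_seed)

  structure(
    list(raw_model = raw_model, H_opt = H_opt,
         rwt_model = rwt_model, H_rwt = report$H_rwt,
         report = report, plan = plan, search = search,
         seeds = list(raw = raw_seed, rwt = rwt_seed),
         data_dim = c(n = data$n, p = data$p)),
    class = "robust_fit"
  )
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("<robust_fit> n = ", x$data_dim["n"], ", p = ", x$data_dim["p"],
      "; |H_opt| = ", length(x$H_opt), ", |H_rwt| = ", length(x$H_rwt),
      "; flagged outliers: ", length(x$report$flagged),
      "; selected features (reweighted): ", sum(x$rwt_model$beta != 0),
      "\n", sep = "")
  invisible(x)
}

#' Indices of features with nonzero slopes
#'
#' @param model A `penalized_model`.
#' @return Integer vector of selected feature indices.
#' @export
selected_features <- function(model) {
  which(model$beta != 0)
}
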