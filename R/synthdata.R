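## Seeded generator of sparse-logistic datasets with label-flip
## contamination. A documented stand-in for mislabeled omics data: features
## are correlated Gaussians, the clean label follows a sparse logistic
## model, and a stated fraction of labels is then flipped (diagnostic
## misclassification affects both classes, so flips are stratified).

#' Generate a sparse-logistic dataset with flipped labels
#'
#' Mechanism: rows of `X` follow a p-variate normal with AR(1) correlation
#' `rho` (unit variances). `q` truly associated features, at evenly spaced
#' positions, carry coefficients of alternating sign and magnitude `effect`;
#' the intercept is calibrated so that the mean class-1 probability equals
#' `balance` on the realized X. Clean labels are Bernoulli draws; then
#' `floor(epsilon * n)` labels, split between the classes proportionally to
#' the class sizes, are flipped.
#'
#' @param n Samples (default 200).
#' @param p Features (default 400).
#' @param q Truly associated features (default 10); `q <= p`.
#' @param effect Common coefficient magnitude of true features (default 2,
#'   on the unit-variance feature scale: a strong, clearly separable
#'   signal).
#' @param rho AR(1) feature correlation in `[0, 1)` (default 0.2).
#' @param epsilon Label-flip fraction in `[0, 0.5)` (default 0.1).
#' @param balance Target class-1 fraction (default 0.5).
#' @param seed Integer seed; the same seed gives a bit-identical dataset.
#' @return Object of class `synthetic_dataset`: `data` (a
#'   [labeled_matrix()] with the contaminated labels), `true_support`
#'   (integer feature indices), `flipped` (integer sample indices),
#'   `clean_y`, `beta_true`, `intercept_true`, and `spec` (the generating
#'   parameters).
#' @export
generate_synthetic <- function(n = 200, p = 400, q = 10, effect = 2,
                               rho = 0.2, epsilon = 0.1, balance = 0.5,
                               seed = 1) {
  if (q > p) stop2("infeasible spec: q > p")
  if (epsilon < 0 || epsilon >= 0.5) stop2("infeasible spec: epsilon must be in [0, 0.5)")
  if (rho < 0 || rho >= 1) stop2("rho must be in [0, 1)")
  if (balance <= 0 || balance >= 1) stop2("balance must be in (0, 1)")
  with_seed(seed, {
    # AR(1) process across columns: exact correlation rho^|j-j'|, unit sd
    X <- matrix(0, n, p)
    X[, 1] <- stats::rnorm(n)
    if (p > 1L) {
      z <- matrix(stats::rnorm(n * (p - 1)), n, p - 1)
      for (j in 2:p) X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * z[, j - 1]
    }
    true_support <- sort(unique(as.integer(round(seq(1, p, length.out = q)))))
    if (length(true_support) < q) { # tiny p: fall back to the first q columns
      true_support <- seq_len(q)
    }
    beta_true <- numeric(p)
    beta_true[true_support] <- effect * rep_len(c(1, -1), q)
    eta0 <- as.numeric(X %*% beta_true)
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta0)) - balance,
                         interval = c(-60, 60), tol = 1e-10)$root
    prob <- stats::plogis(b0 + eta0)
    clean_y <- stats::rbinom(n, 1L, prob)
    # guard: both classes must survive for a usable dataset
    if (length(unique(clean_y)) < 2L) {
      stop2("degenerate draw: clean labels are constant; change seed or balance")
    }
    n_flip <- floor(epsilon * n)
    i1 <- which(clean_y == 1L)
    i0 <- which(clean_y == 0L)
    n1f <- round(n_flip * length(i1) / n)
    n1f <- max(0L, min(n1f, length(i1), n_flip))
    n0f <- min(n_flip - n1f, length(i0))
    n1f <- n_flip - n0f # re-balance if class 0 was too small
    flipped <- sort(c(
      if (n1f > 0L) sample(i1, n1f) else integer(0),
      if (n0f > 0L) sample(i0, n0f) else integer(0)
    ))
    y <- clean_y
    y[flipped] <- 1L - y[flipped]
    data <- labeled_matrix(
      X, y,
      sample_ids = sprintf("s%04d", seq_len(n)),
      feature_ids = sprintf("g%04d", seq_len(p))
    )
    structure(
      list(data = data, true_support = true_support, flipped = flipped,
           clean_y = clean_y, beta_true = beta_true, intercept_true = b0,
           spec = list(n = n, p = p, q = q, effect = effect, rho = rho,
                       epsilon = epsilon, balance = balance, seed = seed)),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> n = ", x$spec$n, ", p = ", x$spec$p,
      "; true support |S| = ", length(x$true_support),
      ", flipped labels: ", length(x$flipped),
      " (epsilon = ", x$spec$epsilon, ", seed = ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Named presets of generator settings
#'
#' `"default"` is the documented stand-in scale used throughout the test
#' suite (n = 200, p = 400). `"paper-scale"` reproduces the headline
#' simulation scale n = 500, p = 1000; the remaining parameters stay at the
#' stand-in defaults because the original simulation design is not public.
#'
#' @param preset Preset name.
#' @return Named list of [generate_synthetic()] arguments.
#' @export
synthetic_preset <- function(preset = c("default", "paper-scale")) {
  preset <- match.arg(preset)
  base <- list(n = 200, p = 400, q = 10, effect = 2, rho = 0.2,
               epsilon = 0.1, balance = 0.5)
  if (preset == "paper-scale") {
    base$n <- 500
    base$p <- 1000
  }
  base
}

#' Write a synthetic dataset as a CSV fixture plus JSON ground truth
#'
#' The CSV holds `sample_id`, the label column, and one column per feature
#' (header row carries the feature identifiers); it round-trips through
#' [read_labeled_matrix()]. The JSON sidecar (`<prefix>_truth.json`)
#' preserves the ground truth exactly: `true_support`, `flipped`, `clean_y`
#' and the generator parameters.
#'
#' @param ds A `synthetic_dataset`.
#' @param prefix Output path prefix (files `<prefix>.csv` and
#'   `<prefix>_truth.json` are written).
#' @param label_col Name of the label column (default `"label"`).
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fixture <- function(ds, prefix, label_col = "label") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  csv <- paste0(prefix, ".csv")
  truth <- paste0(prefix, "_truth.json")
  df <- data.frame(sample_id = ds$data$sample_ids,
                   label = ds$data$y,
                   ds$data$X, check.names = FALSE)
  names(df)[2] <- label_col
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(true_support = ds$true_support, flipped = ds$flipped,
         clean_y = ds$clean_y, spec = ds$spec),
    truth, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv = csv, truth = truth))
}
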