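## Trimming plan arithmetic, the trimmed criterion Q, and stratified
## candidate-subset construction.

#' Trimming plan
#'
#' Given class counts and a retained fraction eta in (0.5, 1], the plan fixes
#' the subset size `h = floor(n * eta)` and its class split: `h1 =
#' floor((n1 + 1) * eta)` capped at `min(h, n1)` retained class-1 samples and
#' `h0 = h - h1` class-0 samples. `1 - eta` is the trimming ratio, the prior
#' guess for the largest plausible outlier fraction.
#'
#' @param n1,n0 Class counts (each >= 2).
#' @param eta Retained fraction in (0.5, 1]. Default 0.75.
#' @return Object of class `trimming_plan` with fields `n`, `n1`, `n0`, `h`,
#'   `h1`, `h0`, `eta`.
#' @export
#' @examples
#' make_plan(250, 250, 0.75) # h = 375
make_plan <- function(n1, n0, eta = 0.75) {
  n1 <- as.integer(n1); n0 <- as.integer(n0)
  if (n1 < 2L || n0 < 2L) stop2("need n1 >= 2 and n0 >= 2")
  if (!is.numeric(eta) || eta <= 0.5 || eta > 1) {
    stop2("eta must lie in (0.5, 1]")
  }
  n <- n1 + n0
  h <- as.integer(floor(n * eta))
  h1 <- as.integer(min(floor((n1 + 1) * eta), n1, h))
  h0 <- h - h1
  if (h1 < 1L || h0 < 1L) stop2("degenerate plan: h1 and h0 must both be >= 1")
  if (h0 > n0) stop2("infeasible plan: h0 = ", h0, " exceeds n0 = ", n0)
  structure(list(n = n, n1 = n1, n0 = n0, h = h, h1 = h1, h0 = h0, eta = eta),
            class = "trimming_plan")
}

#' @export
print.trimming_plan <- function(x, ...) {
  cat("<trimming_plan> eta = ", x$eta, ": keep h = ", x$h, " of n = ", x$n,
      " (h1 = ", x$h1, "/", x$n1, ", h0 = ", x$h0, "/", x$n0, ")\n", sep = "")
  invisible(x)
}

#' Plan for a labeled matrix
#'
#' @param data A [labeled_matrix()].
#' @param eta Retained fraction.
#' @return A [make_plan()] object built from the data's class counts.
#' @export
plan_for_data <- function(data, eta = 0.75) {
  assert_labeled_matrix(data)
  make_plan(data$n1, data$n0, eta)
}

#' Trimmed penalized criterion Q
#'
#' \eqn{Q(H; \beta) = \sum_{i \in H} d_i + |H| \lambda P_\alpha(\beta)}, the
#' objective the subset search minimizes. Deviances come from the model
#' (which may have been fitted on a different subset: that is exactly the
#' quantity the C-step inequality chain compares); the penalty uses the
#' model's standardized-scale slopes and its own (lambda, alpha).
#'
#' @param H Integer index set.
#' @param model A `penalized_model`.
#' @param plan Optional [make_plan()]; if given, `length(H)` must equal
#'   `plan$h`.
#' @return Nonnegative scalar.
#' @export
trim_criterion <- function(H, model, plan = NULL) {
  H <- as.integer(H)
  if (!is.null(plan) && length(H) != plan$h) {
    stop2("subset size ", length(H), " does not match plan h = ", plan$h)
  }
  sum(model$deviances_full[H]) +
    length(H) * model$lam * en_penalty(model$beta, model$alpha)
}

#' Stratified candidate subset of best-fitting observations
#'
#' Returns the `h1` lowest-deviance indices among class-1 samples and the
#' `h0` lowest among class-0 samples, so the class-1 share of the candidate
#' is `h1 / h` by construction. Ties are broken by lower sample index. With
#' `stratified = FALSE` the plain rule is used instead: the `h` smallest
#' deviances regardless of class (the classic C-step candidate).
#'
#' @param deviances Numeric vector of length n.
#' @param y Binary label vector of length n.
#' @param plan A [make_plan()] consistent with `y`'s class counts.
#' @param stratified Keep the class split fixed (default `TRUE`).
#' @return Sorted integer vector of length `plan$h`.
#' @export
select_candidate_subset <- function(deviances, y, plan, stratified = TRUE) {
  if (length(deviances) != length(y)) stop2("deviances and y lengths differ")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (plan$h1 > n1 || plan$h0 > n0) {
    stop2("plan invalid for data: h1 > n1 or h0 > n0")
  }
  if (stratified) {
    i1 <- which(y == 1L)
    i0 <- which(y == 0L)
    # order() is stable, and which() returns increasing indices, so ties
    # resolve to the lower sample index.
    pick1 <- i1[order(deviances[i1])[seq_len(plan$h1)]]
    pick0 <- i0[order(deviances[i0])[seq_len(plan$h0)]]
    sort(c(pick1, pick0))
  } else {
    sort(order(deviances)[seq_len(plan$h)])
  }
}

#' Subset state
#'
#' Bundle of an index set with its fitted model and criterion value.
#'
#' @param H Sorted integer index set.
#' @param model A `penalized_model` fitted on `H`.
#' @param plan Optional plan used for the size check in [trim_criterion()].
#' @return Object of class `subset_state` with `H`, `model`, `Q`, `lam`,
#'   `alpha`.
#' @export
subset_state <- function(H, model, plan = NULL) {
  H <- sort(as.integer(H))
  structure(list(H = H, model = model, Q = trim_criterion(H, model, plan),
                 lam = model$lam, alpha = model$alpha),
            class = "subset_state")
}

#' @export
print.subset_state <- function(x, ...) {
  cat("<subset_state> |H| = ", length(x$H), ", Q = ", signif(x$Q, 8),
      " at lambda = ", signif(x$lam, 4), ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}
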