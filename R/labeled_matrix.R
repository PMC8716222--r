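#' Labeled feature matrix
#'
#' The basic data container: an n x p numeric feature matrix (samples in
#' rows), a binary 0/1 class label per sample, and unique sample/feature
#' identifiers. All downstream functions operate on this object.
#'
#' @param X Numeric matrix, samples in rows, features in columns. No missing
#'   values are allowed.
#' @param y Binary vector of length `nrow(X)` with values in \{0, 1\}; both
#'   classes must be present.
#' @param sample_ids Optional character vector of unique sample identifiers
#'   (default `"s1" ... "sn"` or existing rownames).
#' @param feature_ids Optional character vector of unique feature identifiers
#'   (default `"f1" ... "fp"` or existing colnames).
#'
#' @return An object of class `labeled_matrix`: a list with elements `X`,
#'   `y`, `sample_ids`, `feature_ids`, `n`, `p`, `n1`, `n0`.
#' @export
#' @examples
#' d <- labeled_matrix(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' d$n1
labeled_matrix <- function(X, y, sample_ids = NULL, feature_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop2("length(y) [", length(y), "] must equal nrow(X) [", nrow(X), "]")
  }
  if (anyNA(X)) stop2("feature matrix contains missing values")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    bad <- unique(y[!(y %in% c(0L, 1L))])
    stop2("labels must be 0/1; offending values: ",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L) stop2("both classes must be present (n1 >= 1 and n0 >= 1)")
  sample_ids <- sample_ids %||% rownames(X) %||% paste0("s", seq_len(nrow(X)))
  feature_ids <- feature_ids %||% colnames(X) %||% paste0("f", seq_len(ncol(X)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(X) || anyDuplicated(sample_ids)) {
    stop2("sample_ids must be unique and of length nrow(X)")
  }
  if (length(feature_ids) != ncol(X) || anyDuplicated(feature_ids)) {
    stop2("feature_ids must be unique and of length ncol(X)")
  }
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(
    list(X = X, y = y, sample_ids = sample_ids, feature_ids = feature_ids,
         n = nrow(X), p = ncol(X), n1 = n1, n0 = n0),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat("<labeled_matrix> ", x$n, " samples x ", x$p, " features; class counts: n1 = ",
      x$n1, ", n0 = ", x$n0, "\n", sep = "")
  invisible(x)
}

is_labeled_matrix <- function(x) inherits(x, "labeled_matrix")

assert_labeled_matrix <- function(x) {
  if (!is_labeled_matrix(x)) stop2("expected a labeled_matrix; got ", class(x)[1])
  invisible(x)
}
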