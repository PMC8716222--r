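## Outlier-detection and variable-selection accuracy metrics.

#' Outlier-detection accuracy
#'
#' `Sn` (sensitivity) is the proportion of truly mislabeled samples that were
#' flagged; `FPR` is the proportion of correctly labeled samples that were
#' wrongly flagged. With no truly mislabeled samples `Sn` is undefined and
#' reported as `NA`.
#'
#' @param true_flipped Integer indices of the truly mislabeled samples.
#' @param flagged Integer indices of the flagged samples.
#' @param n Total number of samples.
#' @return List with `Sn` and `FPR`.
#' @export
outlier_metrics <- function(true_flipped, flagged, n) {
  true_flipped <- unique(as.integer(true_flipped))
  flagged <- unique(as.integer(flagged))
  Sn <- if (length(true_flipped) == 0L) NA_real_ else
    length(intersect(flagged, true_flipped)) / length(true_flipped)
  denom <- n - length(true_flipped)
  FPR <- if (denom == 0L) NA_real_ else
    length(setdiff(flagged, true_flipped)) / denom
  list(Sn = Sn, FPR = FPR)
}

#' Variable-selection accuracy
#'
#' `PSR` (positive selection rate) is the proportion of truly associated
#' features that were selected; `FDR` is the proportion of selected features
#' that are not truly associated (0 when nothing is selected: no false
#' discoveries when there are no discoveries); `GM = sqrt(PSR * (1 - FDR))`
#' summarizes both.
#'
#' @param true_support Integer indices of the truly associated features.
#' @param selected Integer indices of the selected features.
#' @return List with `PSR`, `FDR`, `GM`, `model_size`.
#' @export
selection_metrics <- function(true_support, selected) {
  true_support <- unique(as.integer(true_support))
  selected <- unique(as.integer(selected))
  PSR <- if (length(true_support) == 0L) NA_real_ else
    length(intersect(selected, true_support)) / length(true_support)
  FDR <- if (length(selected) == 0L) 0 else
    length(setdiff(selected, true_support)) / length(selected)
  GM <- if (is.na(PSR)) NA_real_ else sqrt(PSR * (1 - FDR))
  list(PSR = PSR, FDR = FDR, GM = GM, model_size = length(selected))
}

#' Average metrics over replicates
#'
#' Fieldwise arithmetic means. `GM` is averaged per replicate — not
#' recomputed from the mean `PSR`/`FDR`, which would differ by a Jensen gap.
#' `NA` fields (e.g. `Sn` under zero contamination) are dropped from their
#' mean.
#'
#' @param per_replicate Non-empty list of metric lists (as returned by
#'   [outlier_metrics()], [selection_metrics()], or a merge of both).
#' @return Named list of means over the union of fields.
#' @export
replicate_summary <- function(per_replicate) {
  if (length(per_replicate) == 0L) stop2("empty replicate list")
  fields <- unique(unlist(lapply(per_replicate, names)))
  out <- lapply(fields, function(f) {
    vals <- vapply(per_replicate,
                   function(r) if (is.null(r[[f]])) NA_real_ else as.numeric(r[[f]]),
                   numeric(1))
    mean(vals, na.rm = TRUE)
  })
  names(out) <- fields
  out
}

#' Write a metrics table as TSV
#'
#' @param metrics A named list (one row) or list of named lists (one row
#'   each).
#' @param path Output file.
#' @param row_names Optional row labels (first column `run`).
#' @return Invisibly, `path`.
#' @export
write_metrics_tsv <- function(metrics, path, row_names = NULL) {
  if (!is.null(names(metrics)) && !is.list(metrics[[1]])) {
    metrics <- list(metrics)
  }
  df <- do.call(rbind, lapply(metrics, function(m) as.data.frame(m)))
  if (!is.null(row_names)) df <- cbind(run = row_names, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
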