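# Overlap test between one region set and another, >= 1 bp, per chromosome.
overlaps_any <- function(regions, calls) {
  if (nrow(regions) == 0L) return(logical(0))
  if (nrow(calls) == 0L) return(rep(FALSE, nrow(regions)))
  q <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  s <- GenomicRanges::GRanges(calls$chrom,
                              IRanges::IRanges(calls$start + 1L, calls$end))
  IRanges::overlapsAny(q, s)
}

#' Evaluate peak calls against labeled regions
#'
#' A labeled peak region counts as a true positive when at least one call
#' with `peak_score >= threshold` overlaps it by at least 1 bp, otherwise
#' a false negative. A labeled noise region overlapped by any such call
#' is a false positive, otherwise a true negative. Each labeled region is
#' judged independently.
#'
#' @param calls A data frame of calls with `chrom`, `start`, `end` and
#'   `peak_score` columns.
#' @param labels A [genomic_regions()] data frame with a `label` column in
#'   `{"peak", "noise"}`.
#' @param threshold Peak-Score cutoff in `[0, 1]`.
#' @return A list of class `evaluation_report`: the 2x2 counts plus
#'   `precision`, `recall` (sensitivity), `selectivity` (specificity) and
#'   `f1`.
#' @export
evaluate_calls <- function(calls, labels, threshold = 0.5) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be a single value in [0, 1]")
  if (nrow(labels) == 0L) stop("`labels` must be non-empty")
  if (!all(labels$label %in% c("peak", "noise")))
    stop("labels must be 'peak' or 'noise'")
  passing <- calls[!is.na(calls$peak_score) &
                   calls$peak_score >= threshold, , drop = FALSE]
  hit <- overlaps_any(labels, passing)
  is_peak <- labels$label == "peak"
  tp <- sum(is_peak & hit); fn <- sum(is_peak & !hit)
  fp <- sum(!is_peak & hit); tn <- sum(!is_peak & !hit)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  selectivity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall,
                 selectivity = selectivity, f1 = f1,
                 threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation at Peak Score >= %.2f\n", x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  selectivity %.4f  F1 %.4f\n",
              x$precision, x$recall, x$selectivity, x$f1))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with the midrank tie correction; used by
#' the synthetic benchmarks.
#'
#' @param scores Numeric scores.
#' @param positive Logical vector, `TRUE` for positives.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
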