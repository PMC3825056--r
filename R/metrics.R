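# Per-sample confusion counts between predicted and reference heart-sound
# segment sets and the four derived percentages: FNR, FPR, ACC, DER.
# Under per-sample scoring ACC + DER == 100 identically.

#' Rasterize a segment set to a 0/1 mask
#'
#' @param segs An `hl_segments` (1-based, half-open intervals).
#' @param n Record length; defaults to the segment set's own `n`.
#' @return Integer vector of 0/1 of length `n`; `mask[i] == 1` iff sample
#'   `i` lies inside a segment.
#' @export
segments_to_mask <- function(segs, n = attr(segs, "n")) {
  mask <- integer(n)
  if (nrow(segs)) for (i in seq_len(nrow(segs))) {
    lo <- max(1L, segs$start[i]); hi <- min(n, segs$end[i] - 1L)
    if (hi >= lo) mask[lo:hi] <- 1L
  }
  mask
}

#' Per-sample confusion counts
#'
#' A true positive is a heart-sound sample detected as heart sound; a
#' false negative a heart-sound sample missed; a false positive a
#' lung-only sample flagged; a true negative a lung-only sample passed.
#'
#' @param pred_mask,truth_mask Equal-length 0/1 vectors.
#' @return List with integer `TP`, `TN`, `FP`, `FN` (summing to the
#'   record length).
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask))
    stop("mask length mismatch", call. = FALSE)
  p <- as.logical(pred_mask); t <- as.logical(truth_mask)
  list(TP = sum(p & t), TN = sum(!p & !t),
       FP = sum(p & !t), FN = sum(!p & t))
}

#' FNR, FPR, ACC and DER from confusion counts
#'
#' `FNR = 100 FN / (FN + TP)`, `FPR = 100 FP / (FP + TN)`,
#' `ACC = 100 (TP + TN) / n`, `DER = 100 (FP + FN) / n`. A zero
#' denominator in FNR or FPR yields `NA`, never a silent 0.
#'
#' @param counts List with `TP`, `TN`, `FP`, `FN`.
#' @return Object of class `hl_metrics`: list with `fnr_pct`, `fpr_pct`,
#'   `acc_pct`, `der_pct` and the `counts`.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    n <- TP + TN + FP + FN
    if (n == 0) stop("empty record: no samples to score", call. = FALSE)
    fnr <- if (FN + TP > 0) 100 * FN / (FN + TP) else NA_real_
    fpr <- if (FP + TN > 0) 100 * FP / (FP + TN) else NA_real_
    structure(list(fnr_pct = fnr, fpr_pct = fpr,
                   acc_pct = 100 * (TP + TN) / n,
                   der_pct = 100 * (FP + FN) / n,
                   counts = list(TP = TP, TN = TN, FP = FP, FN = FN)),
              class = "hl_metrics")
  })
}

#' @export
print.hl_metrics <- function(x, ...) {
  cat(sprintf("FNR %.2f%%  FPR %.2f%%  ACC %.2f%%  DER %.2f%%\n",
              x$fnr_pct, x$fpr_pct, x$acc_pct, x$der_pct))
  invisible(x)
}

#' Score predicted segments against ground truth
#'
#' Per-sample mode (default) rasterizes both sets and scores every
#' sample. Event mode scores whole segments: a truth segment counts as
#' detected (TP) if any predicted segment overlaps it, otherwise missed
#' (FN); a predicted segment overlapping no truth segment is an FP
#' event. Event mode has no TN, so FPR/ACC/DER are `NA` there and the
#' `ACC + DER == 100` identity holds only in sample mode.
#'
#' @param pred Predicted `hl_segments`.
#' @param truth Reference `hl_segments`.
#' @param n Record length (defaults to the sets' `n`).
#' @param mode `"sample"` or `"event"`.
#' @return An `hl_metrics`.
#' @export
evaluate_segments <- function(pred, truth, n = attr(truth, "n"),
                              mode = c("sample", "event")) {
  mode <- match.arg(mode)
  if (mode == "sample") {
    return(compute_metrics(confusion_counts(segments_to_mask(pred, n),
                                            segments_to_mask(truth, n))))
  }
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  tp <- 0L; fn <- 0L
  for (i in seq_len(nrow(truth))) {
    hit <- any(overlaps(truth$start[i], truth$end[i], pred$start, pred$end))
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- 0L
  for (j in seq_len(nrow(pred))) {
    if (!any(overlaps(pred$start[j], pred$end[j], truth$start, truth$end)))
      fp <- fp + 1L
  }
  structure(list(fnr_pct = if (tp + fn > 0) 100 * fn / (tp + fn)
                           else NA_real_,
                 fpr_pct = NA_real_, acc_pct = NA_real_, der_pct = NA_real_,
                 counts = list(TP = tp, TN = NA_integer_, FP = fp, FN = fn)),
            class = "hl_metrics")
}
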