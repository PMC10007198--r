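#' Confusion counts
#'
#' Per-kernel classification outcomes for the fluorescent-vs-non task:
#' TP = fluorescent kernel correctly detected, TN = non-fluorescent
#' kernel correctly passed, FP = false alarm, FN = missed fluorescent
#' kernel.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp = 0L, tn = 0L, fp = 0L, fn = 0L) {
  v <- c(tp, tn, fp, fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

fluorescent_classes <- function() c("mCherry-1", "DsRed-2")

# normalize truths (list of kernel_truth or data.frame) to a data.frame
# with box corners and a fluorescent flag
truths_to_df <- function(truths) {
  if (is.data.frame(truths)) {
    df <- truths
    if (is.null(df$fluorescent)) {
      if (is.null(df$class_label)) stop("truth data needs fluorescent or class_label")
      df$fluorescent <- df$class_label %in% fluorescent_classes()
    }
    return(df)
  }
  data.frame(
    x_min = vapply(truths, function(t) t$bbox[[1]], 0),
    y_min = vapply(truths, function(t) t$bbox[[2]], 0),
    x_max = vapply(truths, function(t) t$bbox[[3]], 0),
    y_max = vapply(truths, function(t) t$bbox[[4]], 0),
    fluorescent = vapply(truths, function(t)
      t$class_label %in% fluorescent_classes(), TRUE))
}

det_box <- function(df, i) bbox(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i])

#' Match detections to ground truth
#'
#' Greedy matching in descending detection score (ties keep input
#' order): each detection claims the unmatched truth with which it has
#' maximal IoU, provided that IoU is at least `iou_thresh`. In the
#' per-kernel classification framing: a matched fluorescent truth is a
#' TP, an unmatched fluorescent truth an FN, a detection not matched to
#' a fluorescent truth an FP, and a non-fluorescent truth with no
#' detection on it a TN.
#'
#' @param dets Data frame of detections with columns
#'   `x_min, y_min, x_max, y_max, score`.
#' @param truths List of `kernel_truth` records, or a data frame with
#'   box columns and either a logical `fluorescent` or a `class_label`
#'   column.
#' @param iou_thresh IoU threshold in `(0, 1)`; 0.5 gives the usual
#'   "AP50" matching.
#' @return A [confusion_counts()] with attribute `"matches"`, an integer
#'   vector giving the matched truth index per detection (NA for
#'   unmatched).
#' @export
match_detections <- function(dets, truths, iou_thresh = 0.5) {
  if (iou_thresh <= 0 || iou_thresh >= 1) stop("iou_thresh must be in (0, 1)")
  tdf <- truths_to_df(truths)
  nd <- if (is.null(dets)) 0L else nrow(dets)
  matched <- rep(NA_integer_, nd)
  taken <- rep(FALSE, nrow(tdf))
  ord <- if (nd > 0L) order(-dets$score, seq_len(nd)) else integer(0)
  for (i in ord) {
    db <- det_box(dets, i)
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nrow(tdf))) {
      if (taken[j]) next
      ov <- iou(db, det_box(tdf, j))
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (!is.na(best_j) && best >= iou_thresh) {
      matched[i] <- best_j
      taken[best_j] <- TRUE
    }
  }
  tp <- sum(taken & tdf$fluorescent)
  fn <- sum(!taken & tdf$fluorescent)
  fp <- sum(is.na(matched) | !tdf$fluorescent[matched])
  tn <- sum(!taken & !tdf$fluorescent)
  cc <- confusion_counts(tp, tn, fp, fn)
  attr(cc, "matches") <- matched
  cc
}

metric_num <- function(num, den, what) {
  if (den == 0) stop(sprintf("%s undefined: zero denominator", what))
  num / den
}

#' Classification metrics from confusion counts
#'
#' Exact rational evaluation of precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and the F1 score
#' (harmonic mean of precision and recall). A zero denominator is an
#' error, never a silent 0.
#'
#' @param cc A [confusion_counts()].
#' @return A number in `[0, 1]`.
#' @examples
#' precision(confusion_counts(480, 480, 20, 20))  # 0.96
#' @export
precision <- function(cc) metric_num(cc$tp, cc$tp + cc$fp, "precision")

#' @rdname precision
#' @export
recall <- function(cc) metric_num(cc$tp, cc$tp + cc$fn, "recall")

#' @rdname precision
#' @export
accuracy <- function(cc)
  metric_num(cc$tp + cc$tn, cc$tp + cc$tn + cc$fp + cc$fn, "accuracy")

#' @rdname precision
#' @export
f1_score <- function(cc) {
  p <- precision(cc); r <- recall(cc)
  if (p + r == 0) stop("f1 undefined: precision + recall is zero")
  2 * p * r / (p + r)
}

#' Precision-recall curve over score thresholds
#'
#' Sweeps the detection score threshold over every distinct score
#' (descending). At each threshold the retained detections are matched
#' greedily (in score order) to the fluorescent truths; precision and
#' recall are cumulative. Recall is non-decreasing as the threshold
#' falls.
#'
#' @inheritParams match_detections
#' @return A list of class `"pr_curve"` with `thresholds`, `precision`
#'   and `recall` vectors of equal length, plus `n_pos`.
#' @export
pr_curve <- function(dets, truths, iou_thresh = 0.5) {
  if (iou_thresh <= 0 || iou_thresh >= 1) stop("iou_thresh must be in (0, 1)")
  tdf <- truths_to_df(truths)
  tdf <- tdf[tdf$fluorescent, , drop = FALSE]
  n_pos <- nrow(tdf)
  if (n_pos == 0L) stop("no fluorescent truths: PR curve undefined")
  nd <- if (is.null(dets)) 0L else nrow(dets)
  if (nd == 0L) {
    return(structure(list(thresholds = numeric(0), precision = numeric(0),
                          recall = numeric(0), n_pos = n_pos),
                     class = "pr_curve"))
  }
  ord <- order(-dets$score, seq_len(nd))
  taken <- rep(FALSE, n_pos)
  is_tp <- logical(nd)
  for (r in seq_along(ord)) {
    i <- ord[r]
    db <- det_box(dets, i)
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(n_pos)) {
      if (taken[j]) next
      ov <- iou(db, det_box(tdf, j))
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (!is.na(best_j) && best >= iou_thresh) {
      taken[best_j] <- TRUE
      is_tp[r] <- TRUE
    }
  }
  scores <- dets$score[ord]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  last <- !duplicated(scores, fromLast = TRUE)   # one point per distinct score
  structure(list(thresholds = scores[last],
                 precision = (cum_tp / (cum_tp + cum_fp))[last],
                 recall = (cum_tp / n_pos)[last],
                 n_pos = n_pos),
            class = "pr_curve")
}

#' Average precision (area under the precision-recall curve)
#'
#' All-points interpolation: precision is replaced by its running
#' maximum from the right (the envelope), and the area is the rectangle
#' sum over recall increments.
#'
#' @param curve A [pr_curve()].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"))
  if (length(curve$recall) == 0L) return(0)
  prec <- rev(cummax(rev(curve$precision)))
  r <- c(0, curve$recall)
  sum(diff(r) * prec)
}
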