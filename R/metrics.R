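# Detection metrics (IoU, precision/recall/F1, average precision, mAP) and
# semantic-segmentation metrics (per-class pixel confusion, mIoU, pixel
# accuracy).

#' Intersection-over-union of two axis-aligned boxes
#'
#' `IoU = area(G ∩ D) / area(G ∪ D)` for corner-format boxes
#' `(x1, y1, x2, y2)`; 0 when the union is empty.
#'
#' @param g,d numeric length-4 vectors, `x1 <= x2`, `y1 <= y2`.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(g, d) {
  iw <- max(0, min(g[3], d[3]) - max(g[1], d[1]))
  ih <- max(0, min(g[4], d[4]) - max(g[2], d[2]))
  inter <- iw * ih
  u <- (g[3] - g[1]) * (g[4] - g[2]) + (d[3] - d[1]) * (d[4] - d[2]) - inter
  if (u <= 0) 0 else inter / u
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching in confidence order: each detection claims
#' its best-overlapping unmatched ground truth, and counts as a true
#' positive only when that IoU is strictly greater than `thr`. Unmatched
#' detections are false positives, unmatched ground truths false
#' negatives.
#'
#' @param dets matrix/data frame with columns `x1, y1, x2, y2, confidence`
#'   (rows need not be pre-sorted).
#' @param gts matrix with columns `x1, y1, x2, y2` (may have zero rows).
#' @param thr IoU threshold in `(0, 1)`.
#' @return list with `counts` (tp/fp/fn) and `tp_flags`, a logical vector in
#'   confidence-descending order.
#' @export
match_detections <- function(dets, gts, thr = 0.5) {
  stopifnot(thr > 0, thr < 1)
  dets <- as.matrix(as.data.frame(dets))
  gts <- as.matrix(gts)
  nd <- nrow(dets)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (nd) dets <- dets[order(dets[, 5], decreasing = TRUE), , drop = FALSE]
  used <- rep(FALSE, max(ng, 0L))
  tp_flags <- logical(nd)
  if (nd && ng) {
    for (i in seq_len(nd)) {
      ious <- vapply(seq_len(ng), function(j)
        box_iou(gts[j, 1:4], dets[i, 1:4]), numeric(1))
      ious[used] <- -1
      j <- which.max(ious)
      if (length(j) && ious[j] > thr) {
        tp_flags[i] <- TRUE
        used[j] <- TRUE
      }
    }
  }
  tp <- sum(tp_flags)
  list(counts = confusion_counts(tp = tp, fp = nd - tp, fn = ng - tp),
       tp_flags = tp_flags)
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative tallies (`tn` is only meaningful for
#'   pixel metrics).
#' @return object of class `fishseg_confusion`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, fn = 0, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "fishseg_confusion")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; degenerate
#' denominators give 0.
#'
#' @param c a [confusion_counts()].
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(c) {
  p <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else 0
  r <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Average precision from a precision-recall curve
#'
#' Area under the interpolated precision-recall curve: the precision
#' envelope is made monotone non-increasing in recall and integrated over
#' all recall change points (all-point interpolation of the definite
#' integral, not 11-point sampling).
#'
#' @param tp_flags logical vector of per-detection true-positive flags in
#'   confidence-descending order.
#' @param n_gt number of ground-truth boxes.
#' @return AP in `[0, 1]`; 0 for an empty curve or `n_gt = 0`.
#' @export
average_precision <- function(tp_flags, n_gt) {
  if (!length(tp_flags) || n_gt == 0) return(0)
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # envelope + integration over recall
  r <- c(0, recall)
  p <- c(1, precision)
  p <- rev(cummax(rev(p)))
  sum(diff(r) * p[-1])
}

#' Mean average precision over classes and IoU thresholds
#'
#' For each class and IoU threshold, detections from all images are pooled
#' in confidence order, matched per image, and integrated into an AP;
#' classes are averaged first, then thresholds. `thresholds = 0.5` gives
#' mAP@0.5; `seq(0.5, 0.95, 0.05)` gives mAP@0.5:0.95.
#'
#' @param dets_by_image list of per-image detection data frames
#'   (`x1, y1, x2, y2, confidence, class_id`).
#' @param gts_by_image list of per-image ground-truth matrices with columns
#'   `x1, y1, x2, y2, class_id`.
#' @param thresholds IoU thresholds in `(0, 1)`.
#' @return mean AP; `NaN` when no ground truth exists anywhere.
#' @export
map_at <- function(dets_by_image, gts_by_image,
                   thresholds = 0.5) {
  stopifnot(length(dets_by_image) == length(gts_by_image),
            all(thresholds > 0), all(thresholds < 1))
  all_cls <- sort(unique(unlist(lapply(gts_by_image, function(g)
    if (length(g)) g[, 5] else NULL))))
  if (!length(all_cls)) return(NaN)
  ap_one <- function(thr, cl) {
    flags <- NULL; confs <- NULL; n_gt <- 0L
    for (i in seq_along(dets_by_image)) {
      d <- dets_by_image[[i]]
      d <- d[d$class_id == cl, , drop = FALSE]
      g <- gts_by_image[[i]]
      g <- if (length(g)) g[g[, 5] == cl, , drop = FALSE] else
        matrix(numeric(0), 0, 5)
      n_gt <- n_gt + nrow(g)
      if (nrow(d)) {
        m <- match_detections(d[, c("x1", "y1", "x2", "y2", "confidence")],
                              g[, 1:4, drop = FALSE], thr)
        flags <- c(flags, m$tp_flags)
        confs <- c(confs, sort(d$confidence, decreasing = TRUE))
      }
    }
    if (is.null(flags)) return(if (n_gt > 0) 0 else NA_real_)
    ord <- order(confs, decreasing = TRUE)
    average_precision(flags[ord], n_gt)
  }
  per_thr <- vapply(thresholds, function(thr) {
    aps <- vapply(all_cls, function(cl) ap_one(thr, cl), numeric(1))
    mean(aps, na.rm = TRUE)
  }, numeric(1))
  mean(per_thr)
}

#' Per-class pixel confusion between predicted and reference masks
#'
#' @param pred,gt integer matrices of class indices (same shape).
#' @param n_classes number of classes (indices `0 .. n_classes-1`).
#' @return list of [confusion_counts()], one per class.
#' @export
seg_confusion <- function(pred, gt, n_classes = 2) {
  if (!all(dim(pred) == dim(gt)))
    stop("argument error: mask shapes differ")
  tot <- length(gt)
  lapply(seq_len(n_classes) - 1L, function(cl) {
    p <- pred == cl
    g <- gt == cl
    tp <- sum(p & g)
    fp <- sum(p & !g)
    fn <- sum(!p & g)
    confusion_counts(tp = tp, fp = fp, fn = fn, tn = tot - tp - fp - fn)
  })
}

#' Mean intersection-over-union across classes
#'
#' `mIoU = mean over classes of TP/(TP+FP+FN)`. A class absent from both
#' masks (empty denominator) contributes 1, the perfect-agreement
#' convention.
#'
#' @param counts list of per-class [confusion_counts()].
#' @return mIoU in `[0, 1]`.
#' @export
miou <- function(counts) {
  ious <- vapply(counts, function(c) {
    d <- c$tp + c$fp + c$fn
    if (d == 0) 1 else c$tp / d
  }, numeric(1))
  mean(ious)
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` over summed pixel tallies.
#'
#' @param counts a single [confusion_counts()] (e.g. the foreground class
#'   of a binary task, whose TN field counts agreeing background pixels).
#' @return accuracy in `[0, 1]`.
#' @export
seg_acc <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  stopifnot(tot > 0)
  (counts$tp + counts$tn) / tot
}
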