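# Decoding raw detection maps into boxes, plus greedy per-class NMS.

sigmoid <- function(x) 1 / (1 + exp(-x))

xywh2xyxy <- function(m) {
  cbind(x1 = m[, 1] - m[, 3] / 2, y1 = m[, 2] - m[, 4] / 2,
        x2 = m[, 1] + m[, 3] / 2, y2 = m[, 2] + m[, 4] / 2)
}

# IoU of one box against many (xyxy matrices)
iou_one_many <- function(b, M) {
  iw <- pmax(0, pmin(b[3], M[, 3]) - pmax(b[1], M[, 1]))
  ih <- pmax(0, pmin(b[4], M[, 4]) - pmax(b[2], M[, 2]))
  inter <- iw * ih
  u <- (b[3] - b[1]) * (b[4] - b[2]) +
    (M[, 3] - M[, 1]) * (M[, 4] - M[, 2]) - inter
  ifelse(u > 0, inter / u, 0)
}

nms_greedy <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord)) {
      ious <- iou_one_many(boxes[i, ], boxes[ord, , drop = FALSE])
      ord <- ord[ious <= iou_thr]
    }
  }
  keep
}

#' Decode raw detection maps and apply non-maximum suppression
#'
#' Applies the grid/anchor transform (sigmoid offsets, anchor-scaled
#' width/height), filters by confidence (objectness times best class
#' score), and greedily suppresses overlapping boxes per class at
#' `IoU > iou_thr`.
#'
#' @param model the `fishseg_model` that produced the outputs (supplies
#'   anchors, strides and image size).
#' @param outputs result of [forward()] (uses `$det_maps`).
#' @param conf_thr,iou_thr confidence and suppression thresholds in `[0, 1]`.
#' @param max_det maximum detections kept per image.
#' @return list (one element per image) of data frames with columns
#'   `x1, y1, x2, y2, confidence, class_id`, sorted by confidence
#'   descending; zero-row frames are allowed.
#' @export
decode_and_nms <- function(model, outputs, conf_thr = 0.25, iou_thr = 0.45,
                           max_det = 300) {
  stopifnot(conf_thr >= 0, conf_thr <= 1, iou_thr >= 0, iou_thr <= 1)
  dm <- outputs$det_maps
  nc <- model$cfg$num_classes
  img <- model$cfg$img_size
  n_img <- dim(dm[[1]])[1]
  anchors <- model$cfg$anchors
  out <- vector("list", n_img)
  for (n in seq_len(n_img)) {
    cand <- NULL
    for (s in seq_along(dm)) {
      dd <- dim(dm[[s]])                      # (N, 3, H, W, 5+nc)
      H <- dd[3]; W <- dd[4]
      a <- array(dm[[s]][n, , , , ], c(3L, H, W, dd[5]))
      stride <- model$strides[s]
      p <- sigmoid(a)
      gx <- array(rep(0:(W - 1), each = 3 * H), c(3, H, W))
      gy <- array(rep(rep(0:(H - 1), each = 3), times = W), c(3, H, W))
      aw <- array(rep(anchors[[s]][, 1], times = H * W), c(3, H, W))
      ah <- array(rep(anchors[[s]][, 2], times = H * W), c(3, H, W))
      x <- (2 * array(p[, , , 1], c(3, H, W)) - 0.5 + gx) * stride
      y <- (2 * array(p[, , , 2], c(3, H, W)) - 0.5 + gy) * stride
      bw <- (2 * array(p[, , , 3], c(3, H, W)))^2 * aw
      bh <- (2 * array(p[, , , 4], c(3, H, W)))^2 * ah
      obj <- as.vector(p[, , , 5])
      clsmat <- matrix(p[, , , 5 + seq_len(nc)], ncol = nc)
      best <- max.col(clsmat, ties.method = "first")
      bestp <- clsmat[cbind(seq_len(nrow(clsmat)), best)]
      conf <- obj * bestp
      sel <- which(conf > conf_thr)
      if (length(sel)) {
        cand <- rbind(cand, cbind(x = as.vector(x)[sel], y = as.vector(y)[sel],
                                  w = as.vector(bw)[sel], h = as.vector(bh)[sel],
                                  conf = conf[sel], cls = best[sel] - 1L))
      }
    }
    if (is.null(cand) || !nrow(cand)) {
      out[[n]] <- data.frame(x1 = numeric(0), y1 = numeric(0),
                             x2 = numeric(0), y2 = numeric(0),
                             confidence = numeric(0), class_id = integer(0))
      next
    }
    bx <- xywh2xyxy(cand[, 1:4, drop = FALSE])
    bx[, c(1, 3)] <- pmin(pmax(bx[, c(1, 3)], 0), img)
    bx[, c(2, 4)] <- pmin(pmax(bx[, c(2, 4)], 0), img)
    keep <- integer(0)
    for (cl in unique(cand[, "cls"])) {
      idx <- which(cand[, "cls"] == cl)
      k <- nms_greedy(bx[idx, , drop = FALSE], cand[idx, "conf"], iou_thr)
      keep <- c(keep, idx[k])
    }
    keep <- keep[order(cand[keep, "conf"], decreasing = TRUE)]
    keep <- head(keep, max_det)
    out[[n]] <- data.frame(x1 = bx[keep, 1], y1 = bx[keep, 2],
                           x2 = bx[keep, 3], y2 = bx[keep, 4],
                           confidence = cand[keep, "conf"],
                           class_id = as.integer(cand[keep, "cls"]))
  }
  out
}
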