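# Losses: focal loss primitives, segmentation cross-entropy, the multitask
# composition, and the full detection loss (CIoU box term, BCE objectness
# with per-scale balance, BCE classification) with analytic gradients with
# respect to the raw detection maps.

#' Foreground probability under the focal-loss convention
#'
#' `pt = p` for foreground (`y = 1`) and `1 - p` for background
#' (`y = -1`).
#'
#' @param p predicted foreground probability in `[0, 1]`.
#' @param y label, `1` (foreground) or `-1` (background).
#' @return probability of the true class.
#' @export
focal_pt <- function(p, y) {
  if (!all(y %in% c(1, -1))) stop("argument error: y must be 1 or -1")
  stopifnot(all(p >= 0), all(p <= 1))
  ifelse(y == 1, p, 1 - p)
}

#' Focal loss
#'
#' Dynamically scaled cross-entropy `-(1 - pt)^gamma * log(pt)`: the
#' modulating factor down-weights well-classified examples, focusing
#' training on hard ones. `gamma = 0` recovers plain cross-entropy. `pt` is
#' clamped at `1e-7` before the logarithm so saturated predictions stay
#' finite.
#'
#' @inheritParams focal_pt
#' @param gamma focusing exponent in `[0, 5]`.
#' @return non-negative loss.
#' @export
focal_loss <- function(p, y, gamma = 1.5) {
  stopifnot(gamma >= 0, gamma <= 5)
  pt <- pmax(focal_pt(p, y), 1e-7)
  -(1 - pt)^gamma * log(pt)
}

#' Semantic segmentation loss
#'
#' Mean per-pixel softmax cross-entropy between a logit map and an integer
#' class mask.
#'
#' @param logits numeric array `(H, W, C)` of unnormalised class scores.
#' @param mask integer matrix `(H, W)` of class indices in
#'   `0 .. C-1`.
#' @return mean cross-entropy (non-negative scalar).
#' @export
seg_loss <- function(logits, mask) {
  d <- dim(logits)
  if (length(d) != 3 || !all(dim(mask) == d[1:2]))
    stop("argument error: logits (H, W, C) and mask (H, W) must agree")
  if (any(mask < 0) || any(mask >= d[3]))
    stop("data error: mask class index out of range")
  lm <- matrix(logits, ncol = d[3])
  mx <- apply(lm, 1, max)
  lse <- mx + log(rowSums(exp(lm - mx)))
  true_logit <- lm[cbind(seq_len(nrow(lm)), as.vector(mask) + 1L)]
  mean(lse - true_logit)
}

#' Multitask loss breakdown
#'
#' Combines the detection components and the segmentation term into the
#' joint objective
#' `total = w_det * (box + objectness + classification) + w_seg * segmentation`.
#'
#' @param box,objectness,classification,segmentation non-negative components.
#' @param weights length-2 numeric `(w_det, w_seg)`.
#' @return object of class `fishseg_loss` with all components and `total`.
#' @export
multitask_loss <- function(box, objectness, classification, segmentation,
                           weights = c(det = 1, seg = 1)) {
  if (any(weights < 0)) stop("config error: loss weights must be >= 0")
  stopifnot(box >= 0, objectness >= 0, classification >= 0,
            segmentation >= 0)
  total <- weights[[1]] * (box + objectness + classification) +
    weights[[2]] * segmentation
  structure(list(box = box, objectness = objectness,
                 classification = classification,
                 segmentation = segmentation,
                 weights = weights, total = total),
            class = "fishseg_loss")
}

#' @export
print.fishseg_loss <- function(x, ...) {
  cat(sprintf("box %.4f  obj %.4f  cls %.4f  seg %.4f  | total %.4f\n",
              x$box, x$objectness, x$classification, x$segmentation,
              x$total))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CIoU and its gradient with respect to the predicted (x, y, w, h).
# alpha is treated as a constant (detached), the usual convention.
ciou_and_grad <- function(pb, tb, eps = 1e-9) {
  px <- pb[, 1]; py <- pb[, 2]; pw <- pb[, 3]; ph <- pb[, 4]
  tx <- tb[, 1]; ty <- tb[, 2]; tw <- tb[, 3]; th <- tb[, 4]
  b1x1 <- px - pw / 2; b1x2 <- px + pw / 2
  b1y1 <- py - ph / 2; b1y2 <- py + ph / 2
  b2x1 <- tx - tw / 2; b2x2 <- tx + tw / 2
  b2y1 <- ty - th / 2; b2y2 <- ty + th / 2
  iw <- pmin(b1x2, b2x2) - pmax(b1x1, b2x1)
  ih <- pmin(b1y2, b2y2) - pmax(b1y1, b2y1)
  pos <- (iw > 0) & (ih > 0)
  I <- pmax(iw, 0) * pmax(ih, 0)
  U <- pw * ph + tw * th - I + eps
  iou <- I / U
  Ax <- as.numeric(b1x2 <= b2x2); Bx <- as.numeric(b1x1 >= b2x1)
  Ay <- as.numeric(b1y2 <= b2y2); By <- as.numeric(b1y1 >= b2y1)
  dI <- cbind(x = (Ax - Bx) * pmax(ih, 0),
              y = (Ay - By) * pmax(iw, 0),
              w = (Ax + Bx) / 2 * pmax(ih, 0),
              h = (Ay + By) / 2 * pmax(iw, 0)) * pos
  dU <- cbind(x = -dI[, 1], y = -dI[, 2], w = ph - dI[, 3], h = pw - dI[, 4])
  diou <- (dI * U - I * dU) / U^2
  # enclosing box diagonal
  cw <- pmax(b1x2, b2x2) - pmin(b1x1, b2x1)
  ch <- pmax(b1y2, b2y2) - pmin(b1y1, b2y1)
  c2 <- cw^2 + ch^2 + eps
  Ex <- as.numeric(b1x2 >= b2x2); Fx <- as.numeric(b1x1 <= b2x1)
  Ey <- as.numeric(b1y2 >= b2y2); Fy <- as.numeric(b1y1 <= b2y1)
  dcw <- cbind(x = Ex - Fx, y = 0, w = (Ex + Fx) / 2, h = 0)
  dch <- cbind(x = 0, y = Ey - Fy, w = 0, h = (Ey + Fy) / 2)
  dc2 <- 2 * cw * dcw + 2 * ch * dch
  rho2 <- (px - tx)^2 + (py - ty)^2
  drho2 <- cbind(x = 2 * (px - tx), y = 2 * (py - ty), w = 0, h = 0)
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  # aspect-ratio consistency term
  delta <- atan(tw / th) - atan(pw / ph)
  v <- (4 / pi^2) * delta^2
  denom <- pw^2 + ph^2 + eps
  dv <- (8 / pi^2) * delta * cbind(x = 0, y = 0, w = -ph / denom,
                                   h = pw / denom)
  alpha <- v / (1 - iou + v + eps)
  ciou <- iou - rho2 / c2 - alpha * v
  list(ciou = ciou, grad = diou - dpen - alpha * dv)
}

# ---------------------------------------------------------------------------
# Target assignment (three scales, anchor-ratio filter, centre + two
# neighbouring cells), in grid units per scale.
build_targets <- function(model, targets, grid_hw, anchor_t = 4) {
  ns <- length(model$strides)
  out <- vector("list", ns)
  if (is.null(targets) || !nrow(targets)) return(out)
  for (s in seq_len(ns)) {
    H <- grid_hw[[s]][1]; W <- grid_hw[[s]][2]
    anc <- model$cfg$anchors[[s]] / model$strides[s]   # grid units
    t <- do.call(rbind, lapply(1:3, function(a)
      cbind(targets, a = a,
            aw = anc[a, 1], ah = anc[a, 2])))
    gw <- t[, "w"] * W; gh <- t[, "h"] * H
    r1 <- gw / t[, "aw"]; r2 <- gh / t[, "ah"]
    keep <- pmax(r1, 1 / r1, r2, 1 / r2) < anchor_t
    t <- t[keep, , drop = FALSE]
    if (!nrow(t)) next
    gx <- t[, "x"] * W; gy <- t[, "y"] * H
    fx <- gx %% 1; fy <- gy %% 1
    cand <- list(
      rep(TRUE, nrow(t)),
      (fx < 0.5) & (gx > 1),          # cell to the left
      (fy < 0.5) & (gy > 1),          # cell above
      (fx >= 0.5) & (gx < W - 1),     # cell to the right
      (fy >= 0.5) & (gy < H - 1))     # cell below
    offs <- list(c(0, 0), c(0.5, 0), c(0, 0.5), c(-0.5, 0), c(0, -0.5))
    rows <- NULL
    for (ci in seq_along(cand)) {
      sel <- which(cand[[ci]])
      if (!length(sel)) next
      gi <- pmin(pmax(floor(gx[sel] - offs[[ci]][1]), 0), W - 1)
      gj <- pmin(pmax(floor(gy[sel] - offs[[ci]][2]), 0), H - 1)
      rows <- rbind(rows, cbind(
        b = t[sel, "img"], a = t[sel, "a"], gi = gi, gj = gj,
        tx = gx[sel] - gi, ty = gy[sel] - gj,
        tw = gw[sel], th = gh[sel],
        cls = t[sel, "cls"], aw = t[sel, "aw"], ah = t[sel, "ah"]))
    }
    out[[s]] <- rows
  }
  out
}

bce_logits <- function(z, t) {
  # numerically stable binary cross-entropy with logits
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# focal modulation of BCE-with-logits (soft targets allowed)
focal_bce_grad <- function(z, t, gamma, alpha = 0.25) {
  p <- sigmoid(z)
  bce <- bce_logits(z, t)
  dbce <- p - t
  if (gamma <= 0) return(list(loss = bce, grad = dbce))
  pt <- t * p + (1 - t) * (1 - p)
  af <- t * alpha + (1 - t) * (1 - alpha)
  modf <- (1 - pt)^gamma
  dpt <- (2 * t - 1) * p * (1 - p)
  loss <- bce * af * modf
  grad <- af * (modf * dbce - bce * gamma * (1 - pt)^(gamma - 1) * dpt)
  list(loss = loss, grad = grad)
}

# Full detection loss over the three raw maps. `targets` is a matrix with
# columns img (1-based), cls (0-based), x, y, w, h (normalised).
# Returns components and the gradient array for each raw map.
detection_loss <- function(model, det_raw, targets, hyp = det_hyp()) {
  nc <- model$cfg$num_classes
  no <- 5L + nc
  ns <- length(det_raw)
  grid_hw <- lapply(det_raw, function(m) dim(m)[1:2])
  assigned <- build_targets(model, targets, grid_hw, hyp$anchor_t)
  lbox <- 0; lobj <- 0; lcls <- 0
  nbox <- 0; ncls <- 0
  grads <- vector("list", ns)
  fl_obj <- hyp$fl_gamma > 0 && "objectness" %in% hyp$fl_targets
  fl_cls <- hyp$fl_gamma > 0 && "classification" %in% hyp$fl_targets
  for (s in seq_len(ns)) {
    raw <- det_raw[[s]]
    d <- dim(raw)                        # (H, W, 3*no, N)
    H <- d[1]; W <- d[2]; N <- d[4]
    g <- array(0, d)
    tobj_key <- NULL; tobj_val <- NULL
    rows <- assigned[[s]]
    if (!is.null(rows) && nrow(rows)) {
      nbox <- nbox + nrow(rows)
      b <- rows[, "b"]; a <- rows[, "a"]
      gi <- rows[, "gi"]; gj <- rows[, "gj"]
      lin <- function(field) {
        ch <- (a - 1) * no + field
        (b - 1) * (H * W * d[3]) + (ch - 1) * (H * W) + gi * H + (gj + 1)
      }
      ix <- lin(1); iy <- lin(2); iw <- lin(3); ih <- lin(4)
      sx <- sigmoid(raw[ix]); sy <- sigmoid(raw[iy])
      sw <- sigmoid(raw[iw]); sh <- sigmoid(raw[ih])
      pb <- cbind(2 * sx - 0.5, 2 * sy - 0.5,
                  (2 * sw)^2 * rows[, "aw"], (2 * sh)^2 * rows[, "ah"])
      tb <- cbind(rows[, "tx"], rows[, "ty"], rows[, "tw"], rows[, "th"])
      cg <- ciou_and_grad(pb, tb)
      lbox_s <- mean(1 - cg$ciou)
      lbox <- lbox + lbox_s
      # d lbox / d raw, chained through the sigmoid decode
      scale <- hyp$box / nrow(rows)
      gx_ <- -cg$grad[, 1] * 2 * sx * (1 - sx) * scale
      gy_ <- -cg$grad[, 2] * 2 * sy * (1 - sy) * scale
      gw_ <- -cg$grad[, 3] * 2 * pb[, 3] * (1 - sw) * scale
      gh_ <- -cg$grad[, 4] * 2 * pb[, 4] * (1 - sh) * scale
      for (pair in list(list(ix, gx_), list(iy, gy_), list(iw, gw_),
                        list(ih, gh_))) {
        agg <- rowsum(pair[[2]], pair[[1]])
        g[as.numeric(rownames(agg))] <- g[as.numeric(rownames(agg))] + agg[, 1]
      }
      # objectness target: the (detached) CIoU, clamped to [0, 1]
      iobj <- lin(5)
      tobj_key <- iobj
      tobj_val <- pmin(pmax(cg$ciou, 0), 1)
      # classification (only meaningful with >1 class)
      if (nc > 1) {
        cls_sum <- 0
        for (cfield in seq_len(nc)) {
          icl <- lin(5 + cfield)
          tcl <- as.numeric(rows[, "cls"] == (cfield - 1))
          fb <- focal_bce_grad(raw[icl], tcl,
                               if (fl_cls) hyp$fl_gamma else 0)
          cls_sum <- cls_sum + sum(fb$loss)
          sc <- hyp$cls / (nrow(rows) * nc)
          agg <- rowsum(fb$grad * sc, icl)
          g[as.numeric(rownames(agg))] <-
            g[as.numeric(rownames(agg))] + agg[, 1]
        }
        lcls <- lcls + cls_sum / (nrow(rows) * nc)
        ncls <- ncls + 1L
      }
    }
    # objectness over every cell of this scale
    obj_ch <- (0:2) * no + 5L
    zobj <- raw[, , obj_ch, , drop = FALSE]
    tobj <- array(0, dim(zobj))
    if (!is.null(tobj_key)) {
      # map full-array linear indices to the obj-channel slice
      base <- (tobj_key - 1)
      n_i <- base %/% (H * W * d[3])
      rem <- base %% (H * W * d[3])
      ch_i <- rem %/% (H * W)
      px_i <- rem %% (H * W)
      a_i <- ch_i %/% no
      slice_lin <- n_i * (H * W * 3) + a_i * (H * W) + px_i + 1
      agg <- tapply(tobj_val, slice_lin, max)
      tobj[as.numeric(names(agg))] <- agg
    }
    fb <- focal_bce_grad(zobj, tobj, if (fl_obj) hyp$fl_gamma else 0)
    lobj <- lobj + mean(fb$loss) * hyp$balance[s]
    gobj <- fb$grad * (hyp$balance[s] * hyp$obj / length(zobj))
    g[, , obj_ch, ] <- g[, , obj_ch, , drop = FALSE] + gobj
    grads[[s]] <- g
  }
  list(box = lbox * hyp$box, objectness = lobj * hyp$obj,
       classification = lcls * hyp$cls,
       grads = grads, n_assigned = nbox)
}

#' Detection loss hyperparameters
#'
#' Gains and settings of the composite detection loss. Focal loss is a
#' switch that defaults to off (`fl_gamma = 0`); when enabled it applies to
#' the targets named in `fl_targets`.
#'
#' @param box,obj,cls component gains.
#' @param fl_gamma focal focusing parameter; 0 disables focal modulation.
#' @param fl_targets which BCE terms focal loss modulates.
#' @param anchor_t anchor-ratio matching threshold.
#' @param balance per-scale objectness balance (strides 8, 16, 32).
#' @return list of hyperparameters.
#' @export
det_hyp <- function(box = 0.05, obj = 1.0, cls = 0.5, fl_gamma = 0,
                    fl_targets = c("objectness", "classification"),
                    anchor_t = 4, balance = c(4, 1, 0.4)) {
  stopifnot(fl_gamma >= 0, fl_gamma <= 5)
  list(box = box, obj = obj, cls = cls, fl_gamma = fl_gamma,
       fl_targets = fl_targets, anchor_t = anchor_t, balance = balance)
}

# Binary segmentation BCE-with-logits on the single foreground logit,
# plus its gradient. masks: (H, W, N) of 0/1; z: (H, W, 1, N).
seg_loss_and_grad <- function(z, masks, w_seg = 1) {
  m <- array(masks, dim(z))
  fb <- focal_bce_grad(z, m, 0)
  list(loss = mean(fb$loss) * w_seg,
       grad = fb$grad * (w_seg / length(z)))
}
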