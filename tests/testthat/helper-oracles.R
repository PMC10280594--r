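# Independent, deliberately naive oracles used to cross-check the package's
# vectorised implementations. These share no code with the package.

# -- closed-form per-layer parameter count from a block's primitive graph ----
oracle_block_params <- function(spec) {
  total <- 0
  for (nd in spec$graph) {
    total <- total + switch(nd$op,
      cbs = nd$c1 * nd$c2 * nd$k^2 + nd$c2 + nd$c2,   # weights + BN scale/shift
      dwcbs = nd$c * nd$k^2 + nd$c + nd$c,
      conv = nd$c1 * nd$c2 * nd$k^2 + nd$c2,          # weights + bias
      0)
  }
  total
}

# instantiated count: length of every weight vector in a built model
oracle_instantiated_params <- function(model) {
  tot <- 0
  for (nd in model$nodes) {
    w <- nd$weights
    if (is.null(w)) next
    for (nm in names(w)) if (!nm %in% c("rm", "rv")) tot <- tot + length(w[[nm]])
  }
  tot
}

# -- naive pixelwise bilinear resample (pixel-centre convention) -------------
oracle_bilinear <- function(grid, out_h, out_w) {
  H <- nrow(grid); W <- ncol(grid)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      sy <- min(max((i - 0.5) * H / out_h - 0.5, 0), H - 1)
      sx <- min(max((j - 0.5) * W / out_w - 0.5, 0), W - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, H - 1); x1 <- min(x0 + 1, W - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <- (1 - fy) * ((1 - fx) * grid[y0 + 1, x0 + 1] +
                               fx * grid[y0 + 1, x1 + 1]) +
                   fy * ((1 - fx) * grid[y1 + 1, x0 + 1] +
                         fx * grid[y1 + 1, x1 + 1])
    }
  }
  out
}

# -- brute-force detection metrics ------------------------------------------
oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# greedy matching + AP by explicit trapezoid-free envelope walk
oracle_ap <- function(flags, n_gt) {
  if (n_gt == 0 || !length(flags)) return(0)
  tp <- 0; fp <- 0
  rec <- numeric(length(flags)); prec <- numeric(length(flags))
  for (i in seq_along(flags)) {
    if (flags[i]) tp <- tp + 1 else fp <- fp + 1
    rec[i] <- tp / n_gt
    prec[i] <- tp / (tp + fp)
  }
  # envelope by explicit max over suffix
  ap <- 0; prev_r <- 0
  for (i in seq_along(flags)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

oracle_match <- function(dets, gts, thr) {
  # dets: matrix x1 y1 x2 y2 conf (any order); gts matrix x1..y2
  if (nrow(dets)) dets <- dets[order(-dets[, 5]), , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  flags <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- oracle_iou(gts[j, 1:4], dets[i, 1:4])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best > thr) { flags[i] <- TRUE; used[bj] <- TRUE }
  }
  flags
}

oracle_map <- function(dets_by_image, gts_by_image, thresholds) {
  classes <- sort(unique(unlist(lapply(gts_by_image, function(g)
    if (length(g)) g[, 5] else NULL))))
  per_thr <- sapply(thresholds, function(thr) {
    aps <- sapply(classes, function(cl) {
      flags <- NULL; confs <- NULL; n_gt <- 0
      for (i in seq_along(dets_by_image)) {
        d <- dets_by_image[[i]]
        d <- d[d$class_id == cl, , drop = FALSE]
        g <- gts_by_image[[i]]
        g <- if (length(g)) g[g[, 5] == cl, , drop = FALSE] else
          matrix(numeric(0), 0, 5)
        n_gt <- n_gt + nrow(g)
        if (nrow(d)) {
          dm <- as.matrix(d[, c("x1", "y1", "x2", "y2", "confidence")])
          fl <- oracle_match(dm, g, thr)
          flags <- c(flags, fl)
          confs <- c(confs, sort(d$confidence, decreasing = TRUE))
        }
      }
      if (is.null(flags)) return(if (n_gt > 0) 0 else NA_real_)
      oracle_ap(flags[order(-confs)], n_gt)
    })
    mean(aps, na.rm = TRUE)
  })
  mean(per_thr)
}

# -- per-pixel segmentation tallies -----------------------------------------
oracle_seg_stats <- function(pred, gt) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    p <- pred[i, j] == 1; g <- gt[i, j] == 1
    if (p && g) tp <- tp + 1
    else if (p && !g) fp <- fp + 1
    else if (!p && g) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# random detection/ground-truth scenario generator used by fuzz tests
random_scenario <- function(n_img = 5, img = 100) {
  gts <- list(); dets <- list()
  for (i in seq_len(n_img)) {
    ng <- sample(0:4, 1)
    g <- NULL
    for (k in seq_len(ng)) {
      x1 <- runif(1, 0, img - 20); y1 <- runif(1, 0, img - 20)
      w <- runif(1, 8, 30); h <- runif(1, 8, 30)
      g <- rbind(g, c(x1, y1, min(x1 + w, img), min(y1 + h, img),
                      sample(0:1, 1)))
    }
    gts[[i]] <- if (is.null(g)) matrix(numeric(0), 0, 5) else g
    nd <- sample(0:6, 1)
    d <- NULL
    for (k in seq_len(nd)) {
      if (ng > 0 && runif(1) < 0.6) {   # jittered copy of a ground truth
        b <- gts[[i]][sample(ng, 1), ]
        jit <- runif(4, -6, 6)
        d <- rbind(d, c(b[1] + jit[1], b[2] + jit[2],
                        max(b[3] + jit[3], b[1] + jit[1] + 2),
                        max(b[4] + jit[4], b[2] + jit[2] + 2),
                        runif(1), b[5]))
      } else {
        x1 <- runif(1, 0, img - 20); y1 <- runif(1, 0, img - 20)
        d <- rbind(d, c(x1, y1, x1 + runif(1, 5, 30), y1 + runif(1, 5, 30),
                        runif(1), sample(0:1, 1)))
      }
    }
    dets[[i]] <- if (is.null(d))
      data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), confidence = numeric(0),
                 class_id = integer(0))
    else
      data.frame(x1 = d[, 1], y1 = d[, 2], x2 = d[, 3], y2 = d[, 4],
                 confidence = d[, 5], class_id = as.integer(d[, 6]))
  }
  list(dets = dets, gts = gts)
}
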