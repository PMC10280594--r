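test_that("box IoU matches hand geometry", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7,
               tolerance = 1e-12)
  expect_equal(box_iou(c(0, 0, 0, 0), c(0, 0, 0, 0)), 0)  # empty union
})

test_that("greedy matching enforces one-to-one assignment", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  d_good <- cbind(1, 1, 10.5, 10.5, 0.9)
  m <- match_detections(d_good, gt, 0.5)
  expect_equal(unlist(m$counts[c("tp", "fp", "fn")]),
               c(tp = 1, fp = 0, fn = 0))
  # IoU below threshold: both a false positive and a false negative
  d_bad <- cbind(6, 6, 16, 16, 0.9)
  m2 <- match_detections(d_bad, gt, 0.5)
  expect_equal(unlist(m2$counts[c("tp", "fp", "fn")]),
               c(tp = 0, fp = 1, fn = 1))
  # two overlapping detections, one ground truth: second is a duplicate
  d_two <- rbind(cbind(0, 0, 10, 10, 0.9), cbind(0.5, 0.5, 10, 10, 0.8))
  m3 <- match_detections(d_two, gt, 0.5)
  expect_equal(unlist(m3$counts[c("tp", "fp", "fn")]),
               c(tp = 1, fp = 1, fn = 0))
  # IoU exactly at the threshold does not count (strictly greater)
  gt4 <- matrix(c(0, 0, 10, 10), 1)
  d4 <- cbind(0, 5, 10, 15, 0.9)    # IoU = 1/3 < 0.5; use thr 1/3
  m4 <- match_detections(d4, gt4, 1 / 3)
  expect_equal(m4$counts$tp, 0)
})

test_that("precision/recall/F1 reproduce the published table cells", {
  # direct recomputation from printed P/R pairs
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.954, 0.930), 3), 0.942)
  expect_equal(round(f1(0.9239, 0.9538), 2), 0.94)
  expect_equal(round(f1(0.954, 0.917), 3), 0.935)
  # and through the confusion-count interface
  prf <- precision_recall_f1(confusion_counts(tp = 930, fp = 45, fn = 70))
  expect_equal(unname(prf["recall"]), 0.930)
  expect_equal(unname(round(prf["f1"], 3)),
               round(f1(930 / 975, 0.93), 3))
  expect_equal(unname(precision_recall_f1(confusion_counts())), c(0, 0, 0))
})

test_that("average precision integrates the interpolated envelope", {
  expect_equal(average_precision(c(TRUE, TRUE, TRUE), 3), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 5), 0)
  expect_equal(average_precision(logical(0), 3), 0)
  # 2 GTs, detections TP(.9) FP(.8) TP(.7): envelope integrates to 5/6
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2), 5 / 6,
               tolerance = 1e-12)
  # confidence rescaling (order-preserving) cannot change AP: flags fixed
  set.seed(20)
  fl <- sample(c(TRUE, FALSE), 30, TRUE)
  expect_equal(average_precision(fl, 12), oracle_ap(fl, 12),
               tolerance = 1e-12)
})

test_that("mAP equals the naive brute-force oracle on random scenarios", {
  set.seed(21)
  for (rep in 1:100) {
    sc <- random_scenario()
    thr <- sample(list(0.5, seq(0.5, 0.95, 0.05)), 1)[[1]]
    got <- map_at(sc$dets, sc$gts, thr)
    want <- oracle_map(sc$dets, sc$gts, thr)
    if (is.nan(want) || is.nan(got)) expect_equal(is.nan(got), is.nan(want))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("mAP@0.5:0.95 never exceeds mAP@0.5", {
  set.seed(22)
  for (rep in 1:25) {
    sc <- random_scenario()
    m50 <- map_at(sc$dets, sc$gts, 0.5)
    m5095 <- map_at(sc$dets, sc$gts, seq(0.5, 0.95, 0.05))
    if (!is.nan(m50)) expect_lte(m5095, m50 + 1e-12)
  }
})

test_that("pixel confusion, mIoU and accuracy match hand counts", {
  # 4x4, GT fish = left half, prediction fish = top half
  gt <- matrix(0L, 4, 4); gt[, 1:2] <- 1L
  pr <- matrix(0L, 4, 4); pr[1:2, ] <- 1L
  cc <- seg_confusion(pr, gt, 2)
  expect_equal(unlist(cc[[2]][c("tp", "fp", "fn", "tn")]),
               c(tp = 4, fp = 4, fn = 4, tn = 4))
  expect_equal(miou(cc), (1 / 3 + 1 / 3) / 2, tolerance = 1e-12)
  expect_equal(seg_acc(cc[[2]]), 0.5)
  # perfect and degenerate cases
  expect_equal(miou(seg_confusion(gt, gt, 2)), 1)
  expect_equal(seg_acc(confusion_counts(tp = 8, tn = 88, fp = 2, fn = 2)),
               0.96)
  all_bg <- matrix(0L, 4, 4)
  cc2 <- seg_confusion(all_bg, all_bg, 2)
  expect_equal(cc2[[2]]$tp, 0)
  expect_equal(cc2[[2]]$tn, 16)
  expect_equal(miou(cc2), 1)    # absent class contributes 1
  # complement prediction on a balanced mask: zero overlap either class
  expect_equal(miou(seg_confusion(1L - gt, gt, 2)), 0)
  expect_error(seg_confusion(matrix(0, 2, 2), matrix(0, 3, 3)),
               "argument error")
})

test_that("pixel metrics equal the per-pixel oracle and are relabel-symmetric", {
  set.seed(23)
  for (rep in 1:20) {
    gt <- matrix(sample(0:1, 64, TRUE), 8, 8)
    pr <- matrix(sample(0:1, 64, TRUE), 8, 8)
    cc <- seg_confusion(pr, gt, 2)
    o <- oracle_seg_stats(pr, gt)
    expect_equal(unlist(cc[[2]][c("tp", "fp", "fn", "tn")]), o)
    # simultaneous class relabel leaves both metrics unchanged
    cc_sw <- seg_confusion(1L - pr, 1L - gt, 2)
    expect_equal(miou(cc), miou(cc_sw), tolerance = 1e-12)
    expect_equal(seg_acc(cc[[2]]), seg_acc(cc_sw[[2]]), tolerance = 1e-12)
  }
})
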