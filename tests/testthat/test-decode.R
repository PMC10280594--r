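make_outputs <- function(model, fill = -10) {
  S <- model$cfg$img_size
  nc <- model$cfg$num_classes
  lapply(model$strides, function(st)
    array(fill, c(1, 3, S / st, S / st, 5 + nc)))
}

test_that("all-low objectness yields an empty detection list", {
  m <- build_model(model_config(img_size = 64), seed = 1)
  out <- list(det_maps = make_outputs(m))
  d <- decode_and_nms(m, out, conf_thr = 0.25, iou_thr = 0.5)
  expect_equal(nrow(d[[1]]), 0)
})

test_that("a single hot cell decodes to the analytic box", {
  m <- build_model(model_config(img_size = 64), seed = 1)
  maps <- make_outputs(m)
  # scale 1 (stride 8), anchor 2 (16x30 px), cell (row 3, col 5): zero
  # offsets decode to centre (grid + 0.5) * stride, size = anchor
  maps[[1]][1, 2, 3, 5, 1:4] <- 0       # sigmoid(0) = 0.5 -> offset +0.5
  maps[[1]][1, 2, 3, 5, 5] <- 10        # objectness ~ 1
  maps[[1]][1, 2, 3, 5, 6] <- 10        # class score ~ 1
  d <- decode_and_nms(m, list(det_maps = maps), conf_thr = 0.5)[[1]]
  expect_equal(nrow(d), 1)
  cx <- (5 - 1 + 0.5) * 8; cy <- (3 - 1 + 0.5) * 8
  expect_equal((d$x1 + d$x2) / 2, cx, tolerance = 1e-9)
  expect_equal((d$y1 + d$y2) / 2, cy, tolerance = 1e-9)
  expect_equal(d$x2 - d$x1, 16, tolerance = 1e-9)   # anchor w
  expect_equal(d$y2 - d$y1, 30, tolerance = 1e-9)   # anchor h
  expect_gt(d$confidence, 0.99)
})

test_that("NMS keeps one of two identical boxes and sorts by confidence", {
  m <- build_model(model_config(img_size = 64), seed = 1)
  maps <- make_outputs(m)
  # identical boxes from two anchors at the same cell, conf ~0.9 / ~0.8
  for (a in 1:2) {
    maps[[1]][1, a, 4, 4, 1:2] <- 0
    # invert anchor scaling so both decode to the same 24x24 px box
    anc <- m$cfg$anchors[[1]][a, ]
    tw <- -log(2 / sqrt(24 / anc[1]) - 1)   # sigmoid^{-1}(sqrt(w/aw)/2)
    th <- -log(2 / sqrt(24 / anc[2]) - 1)
    maps[[1]][1, a, 4, 4, 3] <- tw
    maps[[1]][1, a, 4, 4, 4] <- th
    maps[[1]][1, a, 4, 4, 5] <- if (a == 1) log(0.9 / 0.1) else log(0.8 / 0.2)
    maps[[1]][1, a, 4, 4, 6] <- 20
  }
  d <- decode_and_nms(m, list(det_maps = maps), conf_thr = 0.25,
                      iou_thr = 0.5)[[1]]
  expect_equal(nrow(d), 1)          # self-IoU 1 > 0.5 suppresses the weaker
  expect_equal(d$confidence, 0.9, tolerance = 1e-3)
  # suppression is strict (IoU > thr): at thr 1 both survive, sorted
  d2 <- decode_and_nms(m, list(det_maps = maps), conf_thr = 0.25,
                       iou_thr = 1)[[1]]
  expect_equal(nrow(d2), 2)
  expect_true(all(diff(d2$confidence) <= 0))
})
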