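test_that("focal pt selects the true-class probability", {
  expect_equal(focal_pt(0.3, 1), 0.3)
  expect_equal(focal_pt(0.3, -1), 0.7)
  expect_equal(focal_pt(1.0, 1), 1.0)
  expect_error(focal_pt(0.5, 0), "argument error")
})

test_that("focal loss matches hand values and reduces to cross-entropy", {
  expect_equal(focal_loss(0.5, 1, 0), log(2), tolerance = 1e-12)
  expect_equal(focal_loss(1, 1, 3), 0)
  expect_equal(focal_loss(0.9, 1, 2), 0.1^2 * -log(0.9), tolerance = 1e-9)
  # gamma = 0 is binary cross-entropy for random (p, y)
  set.seed(10)
  p <- runif(1e5, 0.01, 0.99)
  y <- sample(c(1, -1), 1e5, replace = TRUE)
  bce <- ifelse(y == 1, -log(p), -log(1 - p))
  expect_equal(focal_loss(p, y, 0), bce, tolerance = 1e-12)
})

test_that("focal loss is monotone in pt and gamma damps easy examples", {
  pt <- seq(0.05, 0.99, by = 0.01)
  l <- focal_loss(pt, 1, 2)
  expect_true(all(diff(l) < 0))               # decreasing in pt
  for (pt0 in c(0.6, 0.8, 0.95)) {
    ls <- sapply(c(0, 0.5, 1, 2, 5), function(g) focal_loss(pt0, 1, g))
    expect_true(all(diff(ls) < 0))            # higher gamma, smaller loss
  }
  expect_error(focal_loss(0.5, 1, 6), "gamma")
})

test_that("segmentation cross-entropy matches scalar softmax arithmetic", {
  # uniform logits over 2 classes -> ln 2 per pixel
  z <- array(0, c(4, 4, 2))
  mk <- matrix(sample(0:1, 16, TRUE), 4, 4)
  expect_equal(seg_loss(z, mk), log(2), tolerance = 1e-12)
  # strong correct-class margin -> loss ~ 0
  z2 <- array(0, c(2, 2, 2))
  mk2 <- matrix(c(0, 1, 1, 0), 2, 2)
  for (i in 1:2) for (j in 1:2) z2[i, j, mk2[i, j] + 1] <- 50
  expect_lt(seg_loss(z2, mk2), 1e-12)
  # 2x1 hand example: logits (2,0) and (0,2), mask (0,1): both pixels
  # contribute -log(e^2/(e^2+1))
  z3 <- array(0, c(2, 1, 2))
  z3[1, 1, ] <- c(2, 0); z3[2, 1, ] <- c(0, 2)
  mk3 <- matrix(c(0L, 1L), 2, 1)
  expect_equal(seg_loss(z3, mk3), -log(exp(2) / (exp(2) + 1)),
               tolerance = 1e-12)
  expect_error(seg_loss(z3, matrix(c(0L, 2L), 2, 1)), "data error")
})

test_that("the multitask composition obeys its invariant", {
  l <- multitask_loss(1, 2, 3, 4, weights = c(det = 1, seg = 1))
  expect_equal(l$total, 10)
  l2 <- multitask_loss(1, 2, 3, 4, weights = c(det = 1, seg = 0))
  expect_equal(l2$total, 6)                  # detection-only
  expect_equal(multitask_loss(0, 0, 0, 0)$total, 0)
  expect_error(multitask_loss(1, 1, 1, 1, weights = c(-1, 1)),
               "config error")
})

test_that("CIoU gradient matches numerical differentiation (alpha frozen)", {
  fs <- asNamespace("fishseg")
  set.seed(11)
  # independent forward evaluation with frozen alpha for the detach check
  ciou_frozen <- function(pb, tb, alpha) {
    px <- pb[, 1]; py <- pb[, 2]; pw <- pb[, 3]; ph <- pb[, 4]
    tx <- tb[, 1]; ty <- tb[, 2]; tw <- tb[, 3]; th <- tb[, 4]
    I <- pmax(pmin(px + pw / 2, tx + tw / 2) - pmax(px - pw / 2, tx - tw / 2), 0) *
      pmax(pmin(py + ph / 2, ty + th / 2) - pmax(py - ph / 2, ty - th / 2), 0)
    U <- pw * ph + tw * th - I + 1e-9
    cw <- pmax(px + pw / 2, tx + tw / 2) - pmin(px - pw / 2, tx - tw / 2)
    ch <- pmax(py + ph / 2, ty + th / 2) - pmin(py - ph / 2, ty - th / 2)
    v <- (4 / pi^2) * (atan(tw / th) - atan(pw / ph))^2
    I / U - ((px - tx)^2 + (py - ty)^2) / (cw^2 + ch^2 + 1e-9) - alpha * v
  }
  for (rep in 1:30) {
    pb <- matrix(c(runif(2, 0, 10), runif(2, 0.5, 6)), 1)
    tb <- matrix(c(pb[1, 1:2] + runif(2, -2, 2), runif(2, 0.5, 6)), 1)
    r <- fs$ciou_and_grad(pb, tb)
    v0 <- (4 / pi^2) * (atan(tb[3] / tb[4]) - atan(pb[3] / pb[4]))^2
    base <- ciou_frozen(pb, tb, 0)
    iou0 <- NULL
    # recover alpha exactly as the implementation freezes it
    alpha <- local({
      I <- pmax(pmin(pb[1] + pb[3] / 2, tb[1] + tb[3] / 2) -
                  pmax(pb[1] - pb[3] / 2, tb[1] - tb[3] / 2), 0) *
        pmax(pmin(pb[2] + pb[4] / 2, tb[2] + tb[4] / 2) -
               pmax(pb[2] - pb[4] / 2, tb[2] - tb[4] / 2), 0)
      U <- pb[3] * pb[4] + tb[3] * tb[4] - I + 1e-9
      v0 / (1 - I / U + v0 + 1e-9)
    })
    for (k in 1:4) {
      e <- 1e-6
      pp <- pb; pp[1, k] <- pp[1, k] + e
      pm <- pb; pm[1, k] <- pm[1, k] - e
      num <- (ciou_frozen(pp, tb, alpha) - ciou_frozen(pm, tb, alpha)) / (2 * e)
      expect_equal(unname(r$grad[1, k]), unname(num), tolerance = 1e-4)
    }
  }
})

test_that("detection loss gradient matches finite differences of the frozen loss", {
  fs <- asNamespace("fishseg")
  set.seed(12)
  m <- build_model(model_config(img_size = 64), seed = 2)
  raws <- list(array(rnorm(8 * 8 * 18, sd = 0.5), c(8, 8, 18, 1)),
               array(rnorm(4 * 4 * 18, sd = 0.5), c(4, 4, 18, 1)),
               array(rnorm(2 * 2 * 18, sd = 0.5), c(2, 2, 18, 1)))
  targets <- rbind(c(1, 0, 0.4, 0.5, 0.3, 0.25))
  colnames(targets) <- c("img", "cls", "x", "y", "w", "h")
  hyp <- det_hyp()
  dl <- fs$detection_loss(m, raws, targets, hyp)
  # objectness channels carry no detached dependence: straight check
  no <- 6; H <- 8
  obj_idx <- which(array(rep(rep(c(rep(FALSE, 4), TRUE, FALSE), each = 64),
                             3), dim(raws[[1]])))
  set.seed(13)
  for (i in sample(obj_idx, 10)) {
    e <- 1e-5
    rp <- raws; rp[[1]][i] <- rp[[1]][i] + e
    rm_ <- raws; rm_[[1]][i] <- rm_[[1]][i] - e
    f <- function(rw) {
      d <- fs$detection_loss(m, rw, targets, hyp)
      d$box + d$objectness + d$classification
    }
    num <- (f(rp) - f(rm_)) / (2 * e)
    expect_equal(dl$grads[[1]][i], num, tolerance = 1e-4)
  }
})

test_that("zero segmentation weight silences the segmentation gradient", {
  fs <- asNamespace("fishseg")
  z <- array(rnorm(64), c(4, 4, 1, 4))
  mk <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  sl0 <- fs$seg_loss_and_grad(z, mk, 0)
  expect_equal(sl0$loss, 0)
  expect_true(all(sl0$grad == 0))
  sl1 <- fs$seg_loss_and_grad(z, mk, 2)
  expect_gt(max(abs(sl1$grad)), 0)
})
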