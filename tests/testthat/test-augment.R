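toy_sample <- function(S = 32, seed = 1) {
  set.seed(seed)
  img <- array(sample(0:255, S * S * 3, TRUE), c(S, S, 3))
  boxes <- data.frame(class = 0L, cx = 0.2, cy = 0.3, w = 0.2, h = 0.25)
  mask <- matrix(0L, S, S); mask[5:10, 3:8] <- 1L
  image_sample(img, boxes, mask, id = "toy")
}

test_that("deterministic flips reflect boxes and are involutions", {
  s <- toy_sample()
  f <- flip_lr_ud(s, p_lr = 1, p_ud = 0)
  expect_equal(f$boxes$cx, 0.8)
  expect_equal(f$boxes$cy, s$boxes$cy)
  expect_equal(f$image[1, 1, 1], s$image[1, 32, 1])
  ff <- flip_lr_ud(f, p_lr = 1, p_ud = 0)
  expect_identical(ff$image, s$image)
  expect_equal(ff$boxes, s$boxes)
  expect_identical(ff$mask, s$mask)
  # identity at zero probability
  id <- flip_lr_ud(s, 0, 0)
  expect_identical(id$image, s$image)
  # vertical flip reflects cy and the mask rows
  fv <- flip_lr_ud(s, 0, 1)
  expect_equal(fv$boxes$cy, 0.7)
  expect_identical(fv$mask[1, ], s$mask[32, ])
})

test_that("RGB to HSV follows the five-branch hue formula", {
  g <- rgb_to_hsv_deg(100, 100, 100)      # achromatic branch
  expect_equal(g$h, 0); expect_equal(g$s, 0)
  expect_equal(g$v, 100 / 255, tolerance = 1e-12)
  green <- rgb_to_hsv_deg(0, 255, 0)
  expect_equal(green$h, 120); expect_equal(green$s, 1); expect_equal(green$v, 1)
  red <- rgb_to_hsv_deg(255, 0, 0)        # max == R, G >= B branch
  expect_equal(red$h, 0); expect_equal(red$s, 1); expect_equal(red$v, 1)
  magenta_ish <- rgb_to_hsv_deg(255, 0, 10)   # max == R, G < B wraps via 360
  expect_gt(magenta_ish$h, 350)
  blue <- rgb_to_hsv_deg(0, 0, 255)
  expect_equal(blue$h, 240)
})

test_that("HSV round-trip is the identity within one level per channel", {
  set.seed(30)
  r <- sample(0:255, 1e4, TRUE); g <- sample(0:255, 1e4, TRUE)
  b <- sample(0:255, 1e4, TRUE)
  hsv <- rgb_to_hsv_deg(r, g, b)
  back <- hsv_to_rgb_deg(hsv$h, hsv$s, hsv$v)
  expect_lte(max(abs(round(back$r) - r)), 1)
  expect_lte(max(abs(round(back$g) - g)), 1)
  expect_lte(max(abs(round(back$b) - b)), 1)
})

test_that("rgb_to_hsv agrees with the base R reference conversion", {
  set.seed(31)
  r <- sample(0:255, 2000, TRUE); g <- sample(0:255, 2000, TRUE)
  b <- sample(0:255, 2000, TRUE)
  ours <- rgb_to_hsv_deg(r, g, b)
  ref <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  dh <- abs(ours$h - ref[1, ] * 360)
  dh <- pmin(dh, 360 - dh)                # circular distance
  expect_lt(max(dh), 1e-9)
  expect_equal(ours$s, unname(ref[2, ]), tolerance = 1e-12)
  expect_equal(ours$v, unname(ref[3, ]), tolerance = 1e-12)
})

test_that("HSV jitter with zero gains is the identity and preserves range", {
  s <- toy_sample()
  expect_identical(hsv_augment(s$image, c(0, 0, 0)), s$image)
  out <- hsv_augment(s$image, c(0.015, 0.7, 0.4), rng = rng_stream(4))
  expect_equal(dim(out), dim(s$image))
  expect_true(all(out >= 0 & out <= 255))
  expect_true(is.integer(out))
})

test_that("a pure value gain scales a mid-gray image and clips", {
  img <- array(100L, c(4, 4, 3))
  out <- hsv_augment(img, c(0, 0, 0.4), mult = c(1, 1, 1.4))
  expect_true(all(out == 140L))
  img2 <- array(200L, c(4, 4, 3))
  out2 <- hsv_augment(img2, c(0, 0, 0.4), mult = c(1, 1, 1.4))
  expect_true(all(out2 == 255L))            # clipped
})

test_that("mosaic composes four samples with contained, well-formed labels", {
  set.seed(32)
  samples <- lapply(1:4, function(i) toy_sample(seed = i))
  rng <- rng_stream(5)
  mz <- mosaic(samples, 32, rng, quadrant_flip_p = 0, hsv_gains = NULL)
  expect_s3_class(mz, "fishseg_sample")
  expect_equal(dim(mz$image), c(32, 32, 3))
  expect_lte(nrow(mz$boxes), 4)
  if (nrow(mz$boxes)) {
    expect_true(all(mz$boxes$cx - mz$boxes$w / 2 >= -1e-9))
    expect_true(all(mz$boxes$cx + mz$boxes$w / 2 <= 1 + 1e-9))
  }
  expect_equal(dim(mz$mask), c(32, 32))
  # empty-label inputs give an empty mosaic
  empties <- lapply(1:4, function(i) {
    s <- toy_sample(seed = i); s$boxes <- empty_boxes()
    s$mask <- matrix(0L, 32, 32); s
  })
  mz0 <- mosaic(empties, 32, rng_stream(6), quadrant_flip_p = 0)
  expect_equal(nrow(mz0$boxes), 0)
  expect_true(all(mz0$mask == 0))
  # determinism under a fixed stream
  a <- mosaic(samples, 32, rng_stream(7))
  b <- mosaic(samples, 32, rng_stream(7))
  expect_identical(a, b)
  expect_error(mosaic(samples[1:3], 32), "exactly 4")
})

test_that("MixUp endpoints, blending and Beta sampling behave as specified", {
  a <- toy_sample(seed = 1); b <- toy_sample(seed = 2)
  m1 <- mixup(a, b, lambda = 1)
  expect_identical(m1$image, a$image)       # lambda 1 reproduces a
  expect_equal(m1$boxes$weight[seq_len(nrow(a$boxes))], 1)
  expect_equal(m1$boxes$weight[-seq_len(nrow(a$boxes))], 0)
  # pixel arithmetic at lambda 0.5
  a2 <- a; a2$image[] <- 100L
  b2 <- b; b2$image[] <- 200L
  expect_true(all(mixup(a2, b2, lambda = 0.5)$image == 150L))
  # Beta(0.2, 0.2) is symmetric: Monte-Carlo mean 0.5 +- 0.01
  set.seed(33)
  lam <- rbeta(1e5, 0.2, 0.2)
  expect_lt(abs(mean(lam) - 0.5), 0.01)
  sz <- toy_sample(16)
  expect_error(mixup(a, sz), "identical size")
  expect_error(mixup(a, b, alpha = 0.05), "alpha")
})

test_that("operators preserve dtype, size and box normalisation under fuzz", {
  set.seed(34)
  rng <- rng_stream(35)
  for (rep in 1:40) {
    S <- sample(c(16, 32), 1)
    img <- array(sample(0:255, S * S * 3, TRUE), c(S, S, 3))
    nb <- sample(0:3, 1)
    boxes <- if (nb) data.frame(class = 0L, cx = runif(nb, 0.2, 0.8),
                                cy = runif(nb, 0.2, 0.8),
                                w = runif(nb, 0.05, 0.3),
                                h = runif(nb, 0.05, 0.3)) else empty_boxes()
    s <- image_sample(img, boxes, matrix(0L, S, S))
    op <- sample(3, 1)
    out <- switch(op,
      flip_lr_ud(s, 0.5, 0.5, rng),
      { s$image <- hsv_augment(s$image, c(0.015, 0.7, 0.4), rng); s },
      mosaic(list(s, s, s, s), S, rng, quadrant_flip_p = 0.5))
    expect_equal(dim(out$image), c(S, S, 3))
    expect_true(is.integer(out$image))
    expect_true(all(out$image >= 0 & out$image <= 255))
    if (nrow(out$boxes)) {
      expect_true(all(out$boxes$cx - out$boxes$w / 2 >= -1e-9))
      expect_true(all(out$boxes$cy + out$boxes$h / 2 <= 1 + 1e-9))
    }
  }
})
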