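test_that("scene generation is seed-deterministic with exact ground truth", {
  p <- scene_params(img_size = 96, n_fish = 3, occlusion_prob = 0, seed = 42)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(a$boxes, b$boxes)
  expect_equal(nrow(a$boxes), 3)
  # every fish pixel lies inside some box
  px <- which(a$mask == 1, arr.ind = TRUE)
  S <- 96
  inside <- rep(FALSE, nrow(px))
  for (k in seq_len(nrow(a$boxes))) {
    bx <- a$boxes[k, ]
    x1 <- (bx$cx - bx$w / 2) * S; x2 <- (bx$cx + bx$w / 2) * S
    y1 <- (bx$cy - bx$h / 2) * S; y2 <- (bx$cy + bx$h / 2) * S
    inside <- inside | (px[, 2] > x1 - 1e-9 & px[, 2] <= x2 + 1e-9 &
                          px[, 1] > y1 - 1e-9 & px[, 1] <= y2 + 1e-9)
  }
  expect_true(all(inside))
})

test_that("an empty scene has no boxes and an all-background mask", {
  p <- scene_params(img_size = 64, n_fish = 0, seed = 1)
  sc <- generate_scene(p)
  expect_equal(nrow(sc$boxes), 0)
  expect_true(all(sc$mask == 0))
})

test_that("oversized fish are rejected", {
  expect_error(scene_params(img_size = 64, fish_length_px = c(40, 80)),
               "parameter error")
})

test_that("fish are solid shapes: fill fraction and analytic area agree", {
  set.seed(50)
  for (rep in 1:40) {
    p <- scene_params(img_size = 96, n_fish = sample(1:3, 1),
                      occlusion_prob = 0, seed = 1000 + rep)
    sc <- generate_scene(p)
    info <- attr(sc, "fish_info")
    S <- 96
    # box fill fraction: rasterised fish pixels / box area in (0.2, 1]
    for (k in seq_len(nrow(sc$boxes))) {
      bx <- sc$boxes[k, ]
      area_box <- (bx$w * S) * (bx$h * S)
      fill <- info$visible_px[k] / area_box
      expect_gt(fill, 0.2)
      expect_lte(fill, 1.0)
    }
    # unoccluded fish: rendered pixels within 5% of the analytic area
    un <- info[info$visible_px == info$rendered_px, ]
    for (k in seq_len(nrow(un)))
      expect_lt(abs(un$rendered_px[k] - un$analytic_area[k]) /
                  un$analytic_area[k], 0.05)
  }
})

test_that("dataset rendering splits, round-trips and reproduces exactly", {
  dir1 <- file.path(tempdir(), "ds1")
  p <- scene_params(img_size = 64, n_fish = c(1, 3), seed = 7)
  man <- render_dataset(10, c(0.8, 0.1, 0.1), dir1, p)
  expect_equal(as.vector(table(man$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  # floor allocation with remainder to train
  expect_equal(unname(asNamespace("fishseg")$split_counts(100, c(0.8, 0.1, 0.1))),
               c(80L, 10L, 10L))
  expect_equal(unname(asNamespace("fishseg")$split_counts(7, c(0.8, 0.1, 0.1))),
               c(7L, 0L, 0L))
  # loader round-trip: boxes to 1e-6 (fixed-point labels), masks exact
  train <- load_dataset(dir1, "train")
  expect_equal(length(train), 8)
  for (i in seq_along(train)) {
    pp <- p; pp$seed <- p$seed + i
    ref <- generate_scene(pp)
    expect_identical(train[[i]]$image, ref$image)
    expect_identical(train[[i]]$mask, ref$mask)
    expect_equal(nrow(train[[i]]$boxes), nrow(ref$boxes))
    if (nrow(ref$boxes))
      expect_lt(max(abs(as.matrix(train[[i]]$boxes[, 2:5]) -
                          as.matrix(ref$boxes[, 2:5]))), 1e-6)
  }
  # re-rendering with the same seed gives identical checksums
  dir2 <- file.path(tempdir(), "ds2")
  man2 <- render_dataset(10, c(0.8, 0.1, 0.1), dir2, p)
  expect_identical(man$md5, man2$md5)
  unlink(c(dir1, dir2), recursive = TRUE)
})
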