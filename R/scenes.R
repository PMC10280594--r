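# Synthetic aquarium scenes with exact ground truth: elongated fish-shaped
# blobs (rotated ellipse body + triangular tail) over textured tank
# backgrounds, with tight boxes from the rendered pixels and a semantic
# mask marking exactly those pixels.

#' Scene generator parameters
#'
#' Defaults emulate the tank recordings the model family targets: a few
#' golden-hued fish per frame (3-10), body length roughly 15-35% of the
#' frame, elongated 2.2-3.5:1, over a gravel-like background.
#'
#' @param img_size square frame size in pixels.
#' @param n_fish fish count: a single value or an inclusive `(min, max)`
#'   range drawn per scene. May be 0.
#' @param fish_length_px body length range in pixels (`NULL` = 15-35% of
#'   the frame).
#' @param aspect body elongation (length / width) range.
#' @param fish_hue fish hue band in degrees (golden/orange), kept distinct
#'   from the bluish background.
#' @param background `"gravel"`, `"gradient"` or `"noise"`.
#' @param occlusion_prob probability that a fish is deliberately placed
#'   overlapping an earlier one.
#' @param seed integer seed; the same parameters render bit-identical
#'   scenes.
#' @return object of class `fishseg_scene_params`.
#' @export
scene_params <- function(img_size = 640, n_fish = c(3, 10),
                         fish_length_px = NULL, aspect = c(2.2, 3.5),
                         fish_hue = c(20, 50),
                         background = c("gravel", "gradient", "noise"),
                         occlusion_prob = 0.2, seed = 0) {
  background <- match.arg(background)
  if (is.null(fish_length_px))
    fish_length_px <- c(0.15, 0.35) * img_size
  if (length(n_fish) == 1) n_fish <- c(n_fish, n_fish)
  stopifnot(img_size >= 32, all(n_fish >= 0), occlusion_prob >= 0,
            occlusion_prob <= 1, aspect[1] >= 1)
  if (max(fish_length_px) >= img_size)
    stop("parameter error: fish cannot be larger than the frame")
  structure(list(img_size = as.integer(img_size),
                 n_fish = as.integer(n_fish),
                 fish_length_px = fish_length_px, aspect = aspect,
                 fish_hue = fish_hue, background = background,
                 occlusion_prob = occlusion_prob, seed = as.integer(seed)),
            class = "fishseg_scene_params")
}

render_background <- function(p) {
  S <- p$img_size
  if (p$background == "gradient") {
    t <- matrix(rep(seq(0, 1, length.out = S), S), S, S)
    img <- array(0, c(S, S, 3))
    img[, , 1] <- 30 + 30 * t
    img[, , 2] <- 80 + 50 * t
    img[, , 3] <- 120 + 60 * t
  } else if (p$background == "noise") {
    img <- array(0, c(S, S, 3))
    img[, , 1] <- 45; img[, , 2] <- 95; img[, , 3] <- 135
  } else {
    # gravel: coarse random luminance blobs upsampled to full resolution
    cs <- max(4L, S %/% 16L)
    coarse <- array(runif(cs * cs), c(cs, cs, 1L, 1L))
    lum <- cpp_bilinear_fw(coarse, S, S, FALSE)[, , 1, 1]
    img <- array(0, c(S, S, 3))
    img[, , 1] <- 60 + 50 * lum
    img[, , 2] <- 75 + 55 * lum
    img[, , 3] <- 90 + 60 * lum
  }
  img <- img + array(rnorm(S * S * 3, 0, 6), c(S, S, 3))
  pmin(pmax(img, 0), 255)
}

#' Generate one synthetic scene
#'
#' Renders fish sequentially (later fish occlude earlier ones), then
#' derives per-fish boxes as the tight axis-aligned bounds of each fish's
#' visible pixels and the semantic mask as the union of all fish pixels.
#'
#' @param p a [scene_params()].
#' @return an [image_sample()]; attribute `fish_info` holds per-fish
#'   geometry (analytic area, rendered and visible pixel counts).
#' @export
generate_scene <- function(p) {
  stopifnot(inherits(p, "fishseg_scene_params"))
  rng <- rng_stream(p$seed)
  with_rng(rng, {
    S <- p$img_size
    img <- render_background(p)
    id_map <- matrix(0L, S, S)
    n <- if (p$n_fish[1] == p$n_fish[2]) p$n_fish[1] else
      sample(p$n_fish[1]:p$n_fish[2], 1)
    info <- NULL
    centers <- NULL
    for (i in seq_len(n)) {
      len <- runif(1, p$fish_length_px[1], p$fish_length_px[2])
      asp <- runif(1, p$aspect[1], p$aspect[2])
      a <- len / 2; b <- len / (2 * asp)
      tl <- 0.35 * len
      theta <- runif(1, 0, 2 * pi)
      margin <- a + tl + 2
      lo <- min(margin, S / 2); hi <- max(S - margin, S / 2)
      if (!is.null(centers) && runif(1) < p$occlusion_prob) {
        j <- sample(nrow(centers), 1)
        cx <- min(max(centers[j, 1] + runif(1, -a / 2, a / 2), lo), hi)
        cy <- min(max(centers[j, 2] + runif(1, -a / 2, a / 2), lo), hi)
      } else {
        cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
      }
      centers <- rbind(centers, c(cx, cy))
      # window of pixels that can possibly belong to this fish
      r <- a + tl + 1
      xs <- max(1, floor(cx - r)):min(S, ceiling(cx + r))
      ys <- max(1, floor(cy - r)):min(S, ceiling(cy + r))
      gx <- rep(xs, each = length(ys)) - cx
      gy <- rep(ys, times = length(xs)) - cy
      u <- gx * cos(theta) + gy * sin(theta)
      v <- -gx * sin(theta) + gy * cos(theta)
      body <- (u / a)^2 + (v / b)^2 <= 1
      tail_half <- 0.7 * b
      tip <- -0.8 * a
      root <- -a - tl
      tail <- u >= root & u <= tip &
        abs(v) <= tail_half * (tip - u) / (tip - root)
      inside <- body | tail
      if (!any(inside)) next
      rows <- rep(ys, times = length(xs))[inside]
      cols <- rep(xs, each = length(ys))[inside]
      pix <- cbind(rows, cols)
      id_map[pix] <- i
      # golden body colour, brighter towards the head, mild speckle
      hue <- runif(1, p$fish_hue[1], p$fish_hue[2])
      sat <- runif(1, 0.65, 0.9)
      val <- pmin(pmax(0.5 + 0.4 * (u[inside] + a) / (2 * a) +
                         rnorm(sum(inside), 0, 0.04), 0.25), 1)
      rgb <- hsv_to_rgb_deg(rep(hue, sum(inside)), rep(sat, sum(inside)), val)
      img[cbind(rows, cols, 1L)] <- rgb$r
      img[cbind(rows, cols, 2L)] <- rgb$g
      img[cbind(rows, cols, 3L)] <- rgb$b
      info <- rbind(info, data.frame(
        id = i, cx = cx, cy = cy, length = len, aspect = asp, theta = theta,
        analytic_area = pi * a * b + tail_half * (tip - root),
        rendered_px = sum(inside)))
    }
    boxes <- empty_boxes()
    if (!is.null(info)) {
      info$visible_px <- 0L
      keep <- logical(nrow(info))
      for (k in seq_len(nrow(info))) {
        vis <- which(id_map == info$id[k], arr.ind = TRUE)
        info$visible_px[k] <- nrow(vis)
        if (nrow(vis) == 0) next
        keep[k] <- TRUE
        x1 <- min(vis[, 2]) - 1; x2 <- max(vis[, 2])
        y1 <- min(vis[, 1]) - 1; y2 <- max(vis[, 1])
        boxes <- rbind(boxes, data.frame(
          class = 0L, cx = (x1 + x2) / 2 / S, cy = (y1 + y2) / 2 / S,
          w = (x2 - x1) / S, h = (y2 - y1) / S))
      }
      info <- info[keep | TRUE, , drop = FALSE]
    }
    out <- image_sample(array(as.integer(round(img)), c(S, S, 3)), boxes,
                        matrix(as.integer(id_map > 0), S, S),
                        id = sprintf("scene-%d", p$seed))
    attr(out, "fish_info") <- info
    out
  })
}

split_counts <- function(n, ratios) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  nv <- floor(n * ratios[2]); nt <- floor(n * ratios[3])
  c(train = n - nv - nt, val = nv, test = nt)
}

#' Render a synthetic dataset to disk
#'
#' Writes PNG images, YOLO text labels (`class cx cy w h`, 6-decimal fixed
#' point, one line per fish), 8-bit mask PNGs and a `dataset.yaml`, split
#' into train/val/test by floor allocation with the remainder going to
#' train.
#'
#' @param n number of scenes.
#' @param ratios length-3 `(train, val, test)` fractions summing to 1.
#' @param out_dir output directory (created if missing).
#' @param p a [scene_params()]; scene `i` uses seed `p$seed + i`.
#' @return manifest data frame (`file`, `split`, `n_boxes`, `md5`),
#'   invisibly the same content written to `manifest.csv`.
#' @export
render_dataset <- function(n, ratios = c(0.8, 0.1, 0.1), out_dir, p) {
  counts <- split_counts(n, ratios)
  splits <- rep(names(counts), counts)
  for (sub in c("images", "labels", "masks"))
    for (sp in names(counts))
      dir.create(file.path(out_dir, sub, sp), recursive = TRUE,
                 showWarnings = FALSE)
  manifest <- NULL
  for (i in seq_len(n)) {
    pi_ <- p; pi_$seed <- p$seed + i
    sc <- generate_scene(pi_)
    sp <- splits[i]
    stem <- sprintf("scene_%04d", i)
    img_f <- file.path(out_dir, "images", sp, paste0(stem, ".png"))
    lab_f <- file.path(out_dir, "labels", sp, paste0(stem, ".txt"))
    msk_f <- file.path(out_dir, "masks", sp, paste0(stem, ".png"))
    png::writePNG(sc$image / 255, img_f)
    if (nrow(sc$boxes))
      writeLines(sprintf("%d %.6f %.6f %.6f %.6f", sc$boxes$class,
                         sc$boxes$cx, sc$boxes$cy, sc$boxes$w, sc$boxes$h),
                 lab_f)
    else writeLines(character(0), lab_f)
    png::writePNG(sc$mask / 255, msk_f)
    manifest <- rbind(manifest, data.frame(
      file = paste0(stem, ".png"), split = sp, n_boxes = nrow(sc$boxes),
      md5 = unname(tools::md5sum(img_f))))
  }
  yaml::write_yaml(list(path = normalizePath(out_dir),
                        train = "images/train", val = "images/val",
                        test = "images/test", nc = 1L,
                        names = list("fish")),
                   file.path(out_dir, "dataset.yaml"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Load a rendered dataset split
#'
#' Reads back the images, YOLO labels and masks written by
#' [render_dataset()].
#'
#' @param dir dataset directory.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list of [image_sample()]s.
#' @export
load_dataset <- function(dir, split = "train") {
  img_dir <- file.path(dir, "images", split)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  lapply(files, function(f) {
    stem <- sub("\\.png$", "", f)
    im <- png::readPNG(file.path(img_dir, f))
    img <- array(as.integer(round(im * 255)), dim(im))
    lab_f <- file.path(dir, "labels", split, paste0(stem, ".txt"))
    boxes <- empty_boxes()
    if (file.exists(lab_f) && file.size(lab_f) > 0) {
      tb <- read.table(lab_f)
      boxes <- data.frame(class = as.integer(tb[[1]]), cx = tb[[2]],
                          cy = tb[[3]], w = tb[[4]], h = tb[[5]])
    }
    msk_f <- file.path(dir, "masks", split, paste0(stem, ".png"))
    mask <- NULL
    if (file.exists(msk_f)) {
      mm <- png::readPNG(msk_f)
      if (length(dim(mm)) == 3) mm <- mm[, , 1]
      mask <- matrix(as.integer(round(mm * 255)), nrow(mm), ncol(mm))
    }
    image_sample(img, boxes, mask, id = stem)
  })
}
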