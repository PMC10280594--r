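# Training-time data enhancement: label-consistent flips, HSV colour
# jitter, four-image mosaic and MixUp blending, plus the seeded random
# stream they draw from.

#' A labelled image sample
#'
#' One scene: an RGB pixel grid, normalised bounding boxes, and an
#' optional semantic mask.
#'
#' @param image integer array `(H, W, 3)` with values 0-255.
#' @param boxes data frame with columns `class, cx, cy, w, h`, all box
#'   fields normalised to `[0, 1]` (may have zero rows).
#' @param mask optional integer matrix `(H, W)` of class indices
#'   (0 background, 1 fish).
#' @param id identifier string.
#' @return object of class `fishseg_sample`.
#' @export
image_sample <- function(image, boxes = empty_boxes(), mask = NULL,
                         id = "sample") {
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == 3)
  if (!is.null(mask) && !all(dim(mask) == d[1:2]))
    stop("mask must match the image size")
  boxes <- as.data.frame(boxes)
  if (nrow(boxes)) {
    stopifnot(all(c("class", "cx", "cy", "w", "h") %in% names(boxes)))
    vals <- as.matrix(boxes[, c("cx", "cy", "w", "h")])
    if (any(vals < -1e-9) || any(vals > 1 + 1e-9))
      stop("box coordinates must be normalised to [0, 1]")
  }
  structure(list(image = image, boxes = boxes, mask = mask, id = id),
            class = "fishseg_sample")
}

#' @rdname image_sample
#' @export
empty_boxes <- function() {
  data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' @export
print.fishseg_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<sample '%s': %dx%d, %d boxes%s>\n", x$id, d[1], d[2],
              nrow(x$boxes), if (is.null(x$mask)) "" else ", mask"))
  invisible(x)
}

#' Seeded random stream
#'
#' A reproducible pseudo-random source: every stochastic augmentation
#' operator draws only from the stream it is handed, so the same seed and
#' the same call sequence give identical outputs regardless of the global
#' RNG state.
#'
#' @param seed integer seed.
#' @return object of class `fishseg_rng`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(e) <- "fishseg_rng"
  e
}

with_rng <- function(rng, expr) {
  if (is.null(rng)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Random horizontal / vertical flips
#'
#' Flips the image (and mask) left-right with probability `p_lr` and
#' up-down with probability `p_ud`; box centres are reflected
#' (`cx -> 1 - cx`, `cy -> 1 - cy`), widths and heights unchanged.
#'
#' @param s a [image_sample()].
#' @param p_lr,p_ud execution probabilities in `[0, 1]`.
#' @param rng optional [rng_stream()].
#' @return the transformed sample.
#' @export
flip_lr_ud <- function(s, p_lr = 0.5, p_ud = 0.5, rng = NULL) {
  stopifnot(p_lr >= 0, p_lr <= 1, p_ud >= 0, p_ud <= 1)
  u <- with_rng(rng, runif(2))
  if (u[1] < p_lr) {
    s$image <- s$image[, dim(s$image)[2]:1, , drop = FALSE]
    if (!is.null(s$mask)) s$mask <- s$mask[, ncol(s$mask):1, drop = FALSE]
    if (nrow(s$boxes)) s$boxes$cx <- 1 - s$boxes$cx
  }
  if (u[2] < p_ud) {
    s$image <- s$image[dim(s$image)[1]:1, , , drop = FALSE]
    if (!is.null(s$mask)) s$mask <- s$mask[nrow(s$mask):1, , drop = FALSE]
    if (nrow(s$boxes)) s$boxes$cy <- 1 - s$boxes$cy
  }
  s
}

#' RGB to HSV conversion
#'
#' The five-branch hue formula on byte-valued channels: value
#' `V = max(R,G,B)/255`, saturation `S = (max - min)/max` (0 for black),
#' and hue in degrees `[0, 360)` from the dominant channel, with the
#' `G < B` red branch wrapping through 360.
#'
#' @param r,g,b numeric vectors of channel values in 0-255.
#' @return list with components `h` (degrees), `s`, `v` (both in `[0, 1]`).
#' @export
rgb_to_hsv_deg <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  v <- mx / 255
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  d <- mx - mn
  h <- numeric(length(r))
  eq <- d == 0
  isr <- !eq & mx == r
  isg <- !eq & !isr & mx == g
  isb <- !eq & !isr & !isg
  h[isr & g >= b] <- 60 * (g - b)[isr & g >= b] / d[isr & g >= b]
  h[isr & g < b] <- 60 * (g - b)[isr & g < b] / d[isr & g < b] + 360
  h[isg] <- 60 * (b - r)[isg] / d[isg] + 120
  h[isb] <- 60 * (r - g)[isb] / d[isb] + 240
  h[h >= 360] <- 0
  list(h = h, s = s, v = v)
}

#' HSV to RGB conversion
#'
#' Inverse of [rgb_to_hsv_deg()]; channels are returned on the 0-255 scale
#' (not rounded).
#'
#' @param h hue in degrees `[0, 360)`.
#' @param s,v saturation and value in `[0, 1]`.
#' @return list with numeric components `r`, `g`, `b` in `[0, 255]`.
#' @export
hsv_to_rgb_deg <- function(h, s, v) {
  h <- h %% 360
  c_ <- v * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- v - c_
  hi <- floor(h / 60) %% 6
  r <- ifelse(hi == 0 | hi == 5, c_, ifelse(hi == 1 | hi == 4, x, 0))
  g <- ifelse(hi == 1 | hi == 2, c_, ifelse(hi == 0 | hi == 3, x, 0))
  b <- ifelse(hi == 3 | hi == 4, c_, ifelse(hi == 2 | hi == 5, x, 0))
  list(r = (r + m) * 255, g = (g + m) * 255, b = (b + m) * 255)
}

#' HSV colour jitter
#'
#' Draws one multiplier per channel uniformly from `[1 - gain, 1 + gain]`
#' and applies it in HSV space: hue is scaled on its integer half-degree
#' encoding (0-179) and wrapped, saturation and value are scaled and
#' clipped. With all gains zero the image is returned unchanged.
#'
#' @param img integer array `(H, W, 3)`, values 0-255.
#' @param gains numeric length-3 `(h, s, v)` fractional gain limits.
#' @param rng optional [rng_stream()].
#' @param mult optional fixed multipliers (testing hook), length 3.
#' @return integer array of the same shape.
#' @export
hsv_augment <- function(img, gains = c(0.015, 0.7, 0.4), rng = NULL,
                        mult = NULL) {
  stopifnot(all(gains >= 0), length(gains) == 3)
  if (is.null(mult)) {
    u <- with_rng(rng, runif(3, -1, 1))
    mult <- 1 + u * gains
  }
  if (all(mult == 1)) return(img)
  d <- dim(img)
  hsv <- rgb_to_hsv_deg(as.vector(img[, , 1]), as.vector(img[, , 2]),
                        as.vector(img[, , 3]))
  # byte-image hue encoding: degrees / 2 in 0..179, wrapped
  h179 <- (round(hsv$h / 2) * mult[1]) %% 180
  s255 <- pmin(pmax(hsv$s * 255 * mult[2], 0), 255)
  v255 <- pmin(pmax(hsv$v * 255 * mult[3], 0), 255)
  rgb <- hsv_to_rgb_deg(h179 * 2, s255 / 255, v255 / 255)
  out <- array(0L, d)
  out[, , 1] <- as.integer(pmin(pmax(round(rgb$r), 0), 255))
  out[, , 2] <- as.integer(pmin(pmax(round(rgb$g), 0), 255))
  out[, , 3] <- as.integer(pmin(pmax(round(rgb$b), 0), 255))
  out
}

# nearest-neighbour 2x downscale of a matrix / array along H, W
half_nearest <- function(m) {
  if (length(dim(m)) == 2)
    m[seq(1, nrow(m), 2), seq(1, ncol(m), 2), drop = FALSE]
  else
    m[seq(1, dim(m)[1], 2), seq(1, dim(m)[2], 2), , drop = FALSE]
}

half_bilinear_rgb <- function(img) {
  d <- dim(img)
  x <- array(as.numeric(img), c(d[1], d[2], 3L, 1L))
  y <- cpp_bilinear_fw(x, d[1] %/% 2L, d[2] %/% 2L, FALSE)
  array(as.integer(pmin(pmax(round(y), 0), 255)), c(d[1] %/% 2, d[2] %/% 2, 3))
}

#' Four-image mosaic
#'
#' Stitches four samples onto a double-size canvas around a random centre
#' point - top left, top right, bottom left, bottom right - after an
#' optional per-quadrant flip and HSV jitter, remaps boxes and masks to
#' canvas coordinates, then scales the canvas back to `out_size`. Boxes
#' that degenerate below 2 px are dropped.
#'
#' @param samples list of exactly 4 [image_sample()]s, each `out_size`
#'   square.
#' @param out_size output size in pixels (even).
#' @param rng optional [rng_stream()].
#' @param quadrant_flip_p,hsv_gains per-quadrant augmentation settings
#'   (`NULL` gains disable the colour step).
#' @return a single mosaic [image_sample()].
#' @export
mosaic <- function(samples, out_size, rng = NULL, quadrant_flip_p = 0.5,
                   hsv_gains = NULL) {
  if (length(samples) != 4)
    stop("argument error: mosaic requires exactly 4 samples")
  S <- as.integer(out_size)
  canvas <- array(114L, c(2L * S, 2L * S, 3L))
  cmask <- matrix(0L, 2L * S, 2L * S)
  has_mask <- any(!vapply(samples, function(s) is.null(s$mask), logical(1)))
  ctr <- with_rng(rng, round(runif(2, 0.5 * S, 1.5 * S)))
  xc <- ctr[1]; yc <- ctr[2]
  boxes <- NULL
  for (q in 1:4) {
    s <- samples[[q]]
    if (quadrant_flip_p > 0)
      s <- flip_lr_ud(s, quadrant_flip_p, quadrant_flip_p, rng)
    if (!is.null(hsv_gains))
      s$image <- hsv_augment(s$image, hsv_gains, rng)
    h <- dim(s$image)[1]; w <- dim(s$image)[2]
    # canvas placement (x1..x2, y1..y2) and source crop per quadrant
    if (q == 1) { x1 <- max(xc - w, 0); y1 <- max(yc - h, 0); x2 <- xc; y2 <- yc }
    if (q == 2) { x1 <- xc; y1 <- max(yc - h, 0); x2 <- min(xc + w, 2 * S); y2 <- yc }
    if (q == 3) { x1 <- max(xc - w, 0); y1 <- yc; x2 <- xc; y2 <- min(yc + h, 2 * S) }
    if (q == 4) { x1 <- xc; y1 <- yc; x2 <- min(xc + w, 2 * S); y2 <- min(yc + h, 2 * S) }
    cw <- x2 - x1; ch <- y2 - y1
    if (cw <= 0 || ch <= 0) next
    # crop the sample from the side facing the centre
    sx1 <- if (q %in% c(1, 3)) w - cw else 0
    sy1 <- if (q %in% c(1, 2)) h - ch else 0
    canvas[(y1 + 1):y2, (x1 + 1):x2, ] <-
      s$image[(sy1 + 1):(sy1 + ch), (sx1 + 1):(sx1 + cw), ]
    if (has_mask && !is.null(s$mask))
      cmask[(y1 + 1):y2, (x1 + 1):x2] <-
        s$mask[(sy1 + 1):(sy1 + ch), (sx1 + 1):(sx1 + cw)]
    if (nrow(s$boxes)) {
      b <- s$boxes
      # pixel coordinates on the canvas
      bx1 <- (b$cx - b$w / 2) * w - sx1 + x1
      bx2 <- (b$cx + b$w / 2) * w - sx1 + x1
      by1 <- (b$cy - b$h / 2) * h - sy1 + y1
      by2 <- (b$cy + b$h / 2) * h - sy1 + y1
      bx1 <- pmin(pmax(bx1, x1), x2); bx2 <- pmin(pmax(bx2, x1), x2)
      by1 <- pmin(pmax(by1, y1), y2); by2 <- pmin(pmax(by2, y1), y2)
      keep <- (bx2 - bx1) >= 2 & (by2 - by1) >= 2
      if (any(keep))
        boxes <- rbind(boxes, data.frame(
          class = b$class[keep],
          cx = (bx1 + bx2)[keep] / 2, cy = (by1 + by2)[keep] / 2,
          w = (bx2 - bx1)[keep], h = (by2 - by1)[keep]))
    }
  }
  out_img <- half_bilinear_rgb(canvas)
  out_mask <- if (has_mask) half_nearest(cmask) else NULL
  if (!is.null(boxes)) {
    # canvas px -> output px (/2) -> normalised (/S)
    boxes[, c("cx", "cy", "w", "h")] <- boxes[, c("cx", "cy", "w", "h")] / (2 * S)
    keep <- boxes$w * S >= 2 & boxes$h * S >= 2
    boxes <- boxes[keep, , drop = FALSE]
  } else boxes <- empty_boxes()
  image_sample(out_img, boxes, out_mask,
               id = paste0("mosaic-", samples[[1]]$id))
}

#' MixUp blending of two samples
#'
#' Convex pixel blend `lambda * a + (1 - lambda) * b` with
#' `lambda ~ Beta(alpha, alpha)`. Detection boxes cannot be averaged, so
#' both box lists are kept and tagged with loss weights `lambda` and
#' `1 - lambda`; masks are blended as soft class scores and arg-maxed
#' (ties resolve to the first sample's class).
#'
#' @param a,b [image_sample()]s of identical size.
#' @param alpha Beta concentration in `[0.1, 0.4]`.
#' @param rng optional [rng_stream()].
#' @param lambda optional fixed blending coefficient (testing hook).
#' @return blended sample; `boxes` gains a `weight` column.
#' @export
mixup <- function(a, b, alpha = 0.2, rng = NULL, lambda = NULL) {
  stopifnot(alpha >= 0.1, alpha <= 0.4)
  if (!all(dim(a$image) == dim(b$image)))
    stop("argument error: samples must have identical size")
  if (is.null(lambda)) lambda <- with_rng(rng, rbeta(1, alpha, alpha))
  img <- array(as.integer(round(lambda * a$image + (1 - lambda) * b$image)),
               dim(a$image))
  ba <- a$boxes; bb <- b$boxes
  if (nrow(ba)) ba$weight <- lambda
  if (nrow(bb)) bb$weight <- 1 - lambda
  boxes <- rbind(if (nrow(ba)) ba else NULL, if (nrow(bb)) bb else NULL)
  if (is.null(boxes)) { boxes <- empty_boxes(); boxes$weight <- numeric(0) }
  mask <- NULL
  if (!is.null(a$mask) || !is.null(b$mask)) {
    ma <- if (is.null(a$mask)) matrix(0L, nrow(b$mask), ncol(b$mask)) else a$mask
    mb <- if (is.null(b$mask)) matrix(0L, nrow(ma), ncol(ma)) else b$mask
    # soft score for class 1, arg-maxed against class 0; ties -> a's label
    s1 <- lambda * (ma == 1L) + (1 - lambda) * (mb == 1L)
    mask <- matrix(as.integer(s1 > 0.5 | (s1 == 0.5 & ma == 1L)),
                   nrow(ma), ncol(ma))
  }
  out <- image_sample(img, boxes[, c("class", "cx", "cy", "w", "h")], mask,
                      id = paste0("mixup-", a$id))
  out$boxes$weight <- if (nrow(boxes)) boxes$weight else numeric(0)
  out$lambda <- lambda
  out
}

#' Augmentation configuration
#'
#' The published final configuration enables only the HSV jitter and the
#' mosaic (ablation group 8); flips, MixUp and focal loss are available as
#' switches.
#'
#' @param tricks character subset of
#'   `c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp", "Fliplrud")`.
#' @param hsv_gains fractional HSV gain limits `(h, s, v)`.
#' @param p_fliplr,p_flipud flip probabilities when `"Fliplrud"` is active.
#' @param mixup_alpha Beta concentration for MixUp, in `[0.1, 0.4]`.
#' @param mixup_prob probability of applying MixUp to a mosaic pair.
#' @param seed stream seed.
#' @return object of class `fishseg_augment_config`.
#' @export
augment_config <- function(tricks = c("HSV_Aug", "Mosaic"),
                           hsv_gains = c(0.015, 0.7, 0.4),
                           p_fliplr = 0.5, p_flipud = 0.5,
                           mixup_alpha = 0.2, mixup_prob = 0.5,
                           seed = 0) {
  all_tricks <- c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp", "Fliplrud")
  if (!all(tricks %in% all_tricks))
    stop("unknown trick(s): ", paste(setdiff(tricks, all_tricks), collapse = ", "))
  if ("MixUp" %in% tricks && !"Mosaic" %in% tricks)
    stop("config error: MixUp is only used as the Mosaic strategy is enabled")
  stopifnot(mixup_alpha >= 0.1, mixup_alpha <= 0.4,
            all(hsv_gains >= 0), p_fliplr >= 0, p_fliplr <= 1,
            p_flipud >= 0, p_flipud <= 1,
            mixup_prob >= 0, mixup_prob <= 1)
  structure(list(tricks = tricks, hsv_gains = hsv_gains,
                 p_fliplr = p_fliplr, p_flipud = p_flipud,
                 mixup_alpha = mixup_alpha, mixup_prob = mixup_prob,
                 seed = seed),
            class = "fishseg_augment_config")
}

#' Operator plan of an augmentation configuration
#'
#' The ordered list of operators the pipeline will invoke for the given
#' trick set - useful to verify, for example, that the final configuration
#' (HSV + mosaic) never touches the flip or MixUp operators.
#'
#' @param cfg an [augment_config()].
#' @return character vector of operator names.
#' @export
augment_plan <- function(cfg) {
  stopifnot(inherits(cfg, "fishseg_augment_config"))
  plan <- character(0)
  if ("Mosaic" %in% cfg$tricks) plan <- c(plan, "mosaic")
  if ("MixUp" %in% cfg$tricks) plan <- c(plan, "mixup")
  if ("HSV_Aug" %in% cfg$tricks) plan <- c(plan, "hsv_augment")
  if ("Fliplrud" %in% cfg$tricks) plan <- c(plan, "flip_lr_ud")
  plan
}

#' Apply the configured augmentation pipeline
#'
#' Draws what it needs from `pool` (a list of samples): with mosaic
#' enabled, four samples are stitched (and a second mosaic is blended in
#' by MixUp when configured); the HSV jitter and flips then apply to the
#' result. With an empty trick set, zero gains and zero probabilities the
#' pipeline is the identity on `base`.
#'
#' @param base the primary [image_sample()].
#' @param pool list of samples to draw mosaic/MixUp partners from.
#' @param cfg an [augment_config()].
#' @param rng optional [rng_stream()].
#' @return augmented sample.
#' @export
augment_pipeline <- function(base, pool, cfg, rng = NULL) {
  plan <- augment_plan(cfg)
  s <- base
  out_size <- dim(base$image)[1]
  if ("mosaic" %in% plan) {
    pick <- function() pool[[with_rng(rng, sample.int(length(pool), 1))]]
    s <- mosaic(list(base, pick(), pick(), pick()), out_size, rng,
                quadrant_flip_p = if ("flip_lr_ud" %in% plan) cfg$p_fliplr else 0,
                hsv_gains = NULL)
    if ("mixup" %in% plan && with_rng(rng, runif(1)) < cfg$mixup_prob) {
      s2 <- mosaic(list(pick(), pick(), pick(), pick()), out_size, rng,
                   quadrant_flip_p = if ("flip_lr_ud" %in% plan) cfg$p_fliplr else 0,
                   hsv_gains = NULL)
      s <- mixup(s, s2, cfg$mixup_alpha, rng)
    }
  }
  if ("hsv_augment" %in% plan)
    s$image <- hsv_augment(s$image, cfg$hsv_gains, rng)
  if ("flip_lr_ud" %in% plan)
    s <- flip_lr_ud(s, cfg$p_fliplr, cfg$p_flipud, rng)
  s
}
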