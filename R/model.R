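# Assembly of the multitask network: YOLOv5s-v5.0 backbone + PANet neck +
# three-scale detect head, plus a semantic segmentation head tapping the
# neck's stride-8, 512-nominal-channel point (module 16).
#
# The segmentation head's internal widths (one C3/GhostC3 block at c2 = 256,
# SPP to 160, CBS taper 160 -> 88 -> 14, 1x1 projection to a single
# foreground logit) are fixed by calibration against the two published
# totals of the C3- and GhostC3-headed models; see the methods vignette.

default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
}

#' Configuration of the multitask detection + segmentation model
#'
#' Defaults describe the final published variant: the s-scale network
#' (depth 0.33, width 0.50), one detection class (fish), a GhostC3
#' segmentation head tapping module 16 (nominal channel width 512) and
#' HardSwish activations throughout.
#'
#' @param num_classes number of detection classes.
#' @param img_size square input size in pixels, divisible by 32.
#' @param depth_multiple,width_multiple compound scaling factors.
#' @param anchors list of three 3x2 (w, h) pixel anchor matrices, ordered by
#'   scale (stride 8, 16, 32).
#' @param seg_head_variant `"C3"`, `"GhostC3"` or `"none"`.
#' @param seg_classes number of segmentation classes (background + fish).
#' @param activation `"Swish"` or `"HardSwish"`, applied in every CBS block.
#' @param seg_tap_layer module index whose output feeds the segmentation
#'   head (0-based, as modules are conventionally numbered).
#' @param seg_tap_channels nominal (pre-width-scaling) channel width of the
#'   tapped module; checked against the assembled graph.
#' @return an object of class `fishseg_model_config`.
#' @export
model_config <- function(num_classes = 1, img_size = 640,
                         depth_multiple = 0.33, width_multiple = 0.50,
                         anchors = default_anchors(),
                         seg_head_variant = c("GhostC3", "C3", "none"),
                         seg_classes = 2, activation = c("HardSwish", "Swish"),
                         seg_tap_layer = 16, seg_tap_channels = 512) {
  seg_head_variant <- match.arg(seg_head_variant)
  activation <- match.arg(activation)
  if (img_size %% 32 != 0)
    stop("config error: `img_size` must be divisible by 32")
  if (num_classes < 1) stop("config error: `num_classes` must be >= 1")
  if (seg_classes != 2 && seg_head_variant != "none")
    stop("config error: the segmentation head is binary ",
         "(background + fish); `seg_classes` must be 2")
  structure(list(num_classes = as.integer(num_classes),
                 img_size = as.integer(img_size),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 anchors = anchors,
                 seg_head_variant = seg_head_variant,
                 seg_classes = as.integer(seg_classes),
                 activation = activation,
                 seg_tap_layer = as.integer(seg_tap_layer),
                 seg_tap_channels = as.integer(seg_tap_channels)),
            class = "fishseg_model_config")
}

make_divisible <- function(x, div = 8) as.integer(ceiling(x / div) * div)

# nominal module list of the v5.0 s-family graph; `from` uses 0-based module
# indices, -1 = previous
yolo_module_table <- function() {
  list(
    list(kind = "Focus",    from = -1L, c2 = 64L,   k = 3L),
    list(kind = "Conv",     from = -1L, c2 = 128L,  k = 3L, s = 2L),
    list(kind = "C3",       from = -1L, c2 = 128L,  n = 3L, shortcut = TRUE),
    list(kind = "Conv",     from = -1L, c2 = 256L,  k = 3L, s = 2L),
    list(kind = "C3",       from = -1L, c2 = 256L,  n = 9L, shortcut = TRUE),
    list(kind = "Conv",     from = -1L, c2 = 512L,  k = 3L, s = 2L),
    list(kind = "C3",       from = -1L, c2 = 512L,  n = 9L, shortcut = TRUE),
    list(kind = "Conv",     from = -1L, c2 = 1024L, k = 3L, s = 2L),
    list(kind = "SPP",      from = -1L, c2 = 1024L),
    list(kind = "C3",       from = -1L, c2 = 1024L, n = 3L, shortcut = FALSE),
    list(kind = "Conv",     from = -1L, c2 = 512L,  k = 1L, s = 1L),
    list(kind = "Upsample", from = -1L),
    list(kind = "Concat",   from = c(-1L, 6L)),
    list(kind = "C3",       from = -1L, c2 = 512L,  n = 3L, shortcut = FALSE),
    list(kind = "Conv",     from = -1L, c2 = 256L,  k = 1L, s = 1L),
    list(kind = "Upsample", from = -1L),
    list(kind = "Concat",   from = c(-1L, 4L)),
    list(kind = "C3",       from = -1L, c2 = 256L,  n = 3L, shortcut = FALSE),
    list(kind = "Conv",     from = -1L, c2 = 256L,  k = 3L, s = 2L),
    list(kind = "Concat",   from = c(-1L, 14L)),
    list(kind = "C3",       from = -1L, c2 = 512L,  n = 3L, shortcut = FALSE),
    list(kind = "Conv",     from = -1L, c2 = 512L,  k = 3L, s = 2L),
    list(kind = "Concat",   from = c(-1L, 10L)),
    list(kind = "C3",       from = -1L, c2 = 1024L, n = 3L, shortcut = FALSE)
  )
}

# segmentation head primitives appended after the tap. At the reference
# width (256 tapped channels, i.e. width_multiple 0.5) the widths are the
# calibrated ones; at other model widths they scale proportionally (kept
# even for the Ghost split).
seg_head_plan <- function(variant, c_tap = 256L) {
  r <- c_tap / 256
  sc <- function(c) max(2L, as.integer(2 * round(c * r / 2)))
  list(variant = variant,
       c3 = list(c1 = c_tap, c2 = sc(256), n = 1L),
       spp = list(c1 = sc(256), c2 = sc(160)),
       taper = list(list(c1 = sc(160), c2 = sc(160), k = 3L),
                    list(c1 = sc(160), c2 = sc(88),  k = 1L),
                    list(c1 = sc(88),  c2 = sc(14),  k = 3L)),
       proj = list(c1 = sc(14), c2 = 1L))
}

#' Build the multitask model
#'
#' Assembles the backbone, neck, detect head and (optionally) the
#' segmentation head into an executable layer graph and initialises
#' trainable weights.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialisation (reproducible builds);
#'   `NULL` leaves the R random stream untouched.
#' @return an object of class `fishseg_model`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "fishseg_model_config"))
  gd <- cfg$depth_multiple; gw <- cfg$width_multiple
  act <- cfg$activation
  mods <- yolo_module_table()
  if (cfg$seg_tap_layer < 0 || cfg$seg_tap_layer >= length(mods))
    stop("config error: `seg_tap_layer` out of range")

  g <- graph_new()
  input <- graph_add(g, "input", integer(0), c = 3L)
  mod_out <- integer(length(mods))   # graph node of each module's output
  mod_c2 <- integer(length(mods))    # actual channels
  mod_stride <- integer(length(mods))
  mod_nodes0 <- integer(length(mods))
  nom_c2 <- integer(length(mods))    # nominal (pre-scaling) channels
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    # `from` is 0-based with -1 = previous module; map to 1-based, 0 = input
    fr <- vapply(m$from, function(f) if (f == -1L) i - 1L else f + 1L,
                 integer(1))
    src <- vapply(fr, function(f) if (f == 0L) input else mod_out[f],
                  integer(1))
    c1 <- if (fr[1L] == 0L) 3L else mod_c2[fr[1L]]
    st <- if (fr[1L] == 0L) 1L else mod_stride[fr[1L]]
    nom_c2[i] <- if (m$kind %in% c("Upsample", "Concat"))
      sum(ifelse(fr == 0L, 3L, nom_c2[pmax(fr, 1L)])) else m$c2
    mod_nodes0[i] <- length(g$nodes) + 1L
    out <- switch(m$kind,
      Focus = {
        c2 <- make_divisible(m$c2 * gw); st <- 2L
        build_focus(g, src[1L], c1, c2, m$k, act)
      },
      Conv = {
        c2 <- make_divisible(m$c2 * gw); if (m$s == 2L) st <- st * 2L
        build_cbs(g, src[1L], c1, c2, m$k, m$s, act)
      },
      C3 = {
        c2 <- make_divisible(m$c2 * gw)
        n <- max(1L, round(m$n * gd))
        build_c3(g, src[1L], c1, c2, n, m$shortcut, act)
      },
      SPP = {
        c2 <- make_divisible(m$c2 * gw)
        build_spp(g, src[1L], c1, c2, c(1L, 5L, 9L, 13L), act)
      },
      Upsample = {
        c2 <- c1; st <- st %/% 2L
        graph_add(g, "up_nearest2", src[1L], c = c1)
      },
      Concat = {
        c2 <- sum(mod_c2[fr])
        graph_add(g, "concat", src)
      },
      stop("unknown module kind ", m$kind))
    mod_out[i] <- out; mod_c2[i] <- c2; mod_stride[i] <- st
  }

  # detect head: one biased 1x1 conv per scale (modules 17, 20, 23, 0-based)
  det_from <- c(18L, 21L, 24L)   # 1-based module indices
  no <- 3L * (5L + cfg$num_classes)
  det_nodes <- vapply(det_from, function(mi) {
    graph_add(g, "conv", mod_out[mi], c1 = mod_c2[mi], c2 = no, k = 1L, s = 1L)
  }, integer(1))

  seg_node <- NA_integer_
  seg_nodes0 <- NA_integer_
  if (cfg$seg_head_variant != "none") {
    tap_mod <- cfg$seg_tap_layer + 1L
    if (nom_c2[tap_mod] != cfg$seg_tap_channels)
      stop("config error: tapped module has nominal width ", nom_c2[tap_mod],
           ", expected `seg_tap_channels` = ", cfg$seg_tap_channels)
    tap <- mod_out[tap_mod]
    c_tap <- mod_c2[tap_mod]
    plan <- seg_head_plan(cfg$seg_head_variant, c_tap)
    seg_nodes0 <- length(g$nodes) + 1L
    h <- if (cfg$seg_head_variant == "GhostC3")
      build_ghostc3(g, tap, plan$c3$c1, plan$c3$c2, plan$c3$n, act)
    else
      build_c3(g, tap, plan$c3$c1, plan$c3$c2, plan$c3$n, TRUE, act)
    h <- build_spp(g, h, plan$spp$c1, plan$spp$c2, c(1L, 5L, 9L, 13L), act)
    for (tp in plan$taper) {
      h <- build_cbs(g, h, tp$c1, tp$c2, tp$k, 1L, act)
      h <- graph_add(g, "up_bilinear2", h, c = tp$c2)
    }
    seg_node <- graph_add(g, "conv", h, c1 = plan$proj$c1, c2 = plan$proj$c2,
                          k = 1L, s = 1L)
  }

  model <- structure(list(cfg = cfg, nodes = g$nodes, input = input,
                          det_nodes = det_nodes, seg_node = seg_node,
                          mod_out = mod_out, mod_c2 = mod_c2,
                          mod_stride = mod_stride, mod_nodes0 = mod_nodes0,
                          seg_nodes0 = seg_nodes0,
                          strides = c(8L, 16L, 32L)),
                     class = "fishseg_model")
  init_weights(model, seed = seed)
}

#' @export
print.fishseg_model <- function(x, ...) {
  cat(sprintf(paste0("<fishseg multitask model: %d classes, img %d, ",
                     "seg head %s, %s activations, %s parameters>\n"),
              x$cfg$num_classes, x$cfg$img_size, x$cfg$seg_head_variant,
              x$cfg$activation,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

init_weights <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- model$cfg$num_classes
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    w <- switch(nd$op,
      cbs = {
        fan_in <- nd$c1 * nd$k^2
        list(W = matrix(runif(nd$k^2 * nd$c1 * nd$c2, -1, 1) / sqrt(fan_in),
                        nd$k^2 * nd$c1, nd$c2),
             gamma = rep(1, nd$c2), beta = rep(0, nd$c2),
             rm = rep(0, nd$c2), rv = rep(1, nd$c2))
      },
      dwcbs = {
        list(W = matrix(runif(nd$k^2 * nd$c, -1, 1) / nd$k, nd$k^2, nd$c),
             gamma = rep(1, nd$c), beta = rep(0, nd$c),
             rm = rep(0, nd$c), rv = rep(1, nd$c))
      },
      conv = {
        fan_in <- nd$c1 * nd$k^2
        list(W = matrix(runif(nd$k^2 * nd$c1 * nd$c2, -1, 1) / sqrt(fan_in),
                        nd$k^2 * nd$c1, nd$c2),
             b = runif(nd$c2, -1, 1) / sqrt(fan_in))
      },
      NULL)
    model$nodes[[i]]$weights <- w
  }
  # detection bias prior: start objectness low (few objects per cell) and
  # class scores high, the usual single-stage warm start
  for (s in seq_along(model$det_nodes)) {
    i <- model$det_nodes[s]
    stride <- model$strides[s]
    b <- model$nodes[[i]]$weights$b
    no <- 5L + nc
    for (a in 0:2) {
      b[a * no + 5L] <- log(8 / (model$cfg$img_size / stride)^2)
      if (nc >= 1)
        b[a * no + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99 + 1e-16))
    }
    model$nodes[[i]]$weights$b <- b
  }
  model
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: convolution weights, biases of the
#' detect/projection convolutions, and the per-channel scale and shift of
#' every batch normalisation. Running batch-norm statistics are not
#' trainable and are excluded.
#'
#' @param model a `fishseg_model`.
#' @return integer count.
#' @examples
#' \donttest{
#' m <- build_model(model_config(seg_head_variant = "C3"), seed = 1)
#' count_parameters(m)   # 7731361
#' }
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "fishseg_model"))
  sum(vapply(model$nodes, function(nd) {
    if (is.null(nd$weights)) 0
    else sum(vapply(nd$weights[setdiff(names(nd$weights), c("rm", "rv"))],
                    length, numeric(1)))
  }, numeric(1)))
}

#' Per-module parameter table
#'
#' @param model a `fishseg_model`.
#' @return data frame with one row per module (backbone/neck modules, the
#'   three detect convolutions, and the segmentation head as a whole).
#' @export
param_table <- function(model) {
  stopifnot(inherits(model, "fishseg_model"))
  node_p <- vapply(model$nodes, prim_params, numeric(1))
  kinds <- vapply(yolo_module_table(), `[[`, character(1), "kind")
  n_mod <- length(model$mod_nodes0)
  rows <- data.frame(
    module = seq_len(n_mod) - 1L,
    kind = kinds,
    channels = model$mod_c2,
    stride = model$mod_stride,
    params = vapply(seq_len(n_mod), function(i) {
      lo <- model$mod_nodes0[i]
      hi <- if (i < n_mod) model$mod_nodes0[i + 1L] - 1L else
        min(model$det_nodes, model$seg_nodes0, na.rm = TRUE) - 1L
      sum(node_p[lo:hi])
    }, numeric(1)))
  det <- data.frame(module = n_mod - 1L + seq_along(model$det_nodes),
                    kind = "Detect", channels = NA_integer_,
                    stride = model$strides,
                    params = node_p[model$det_nodes])
  out <- rbind(rows, det)
  if (!is.na(model$seg_node)) {
    seg_idx <- setdiff(model$seg_nodes0:length(model$nodes), model$det_nodes)
    out <- rbind(out, data.frame(module = max(out$module) + 1L,
                                 kind = paste0("SegHead(",
                                               model$cfg$seg_head_variant, ")"),
                                 channels = 1L, stride = 1L,
                                 params = sum(node_p[seg_idx])))
  }
  out
}

#' Write / read a model configuration as YAML
#'
#' Round-trips the [model_config()] fields through the conventional
#' model-description YAML dialect (scaling multiples, anchors by scale,
#' head variant and activation, plus a `seg_head` section).
#'
#' @param cfg a [model_config()].
#' @param path YAML file path.
#' @return `model_config_from_yaml` returns the reconstructed config.
#' @export
model_config_to_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "fishseg_model_config"))
  y <- list(nc = cfg$num_classes, img_size = cfg$img_size,
            depth_multiple = cfg$depth_multiple,
            width_multiple = cfg$width_multiple,
            anchors = lapply(cfg$anchors, function(a) as.vector(t(a))),
            activation = cfg$activation,
            seg_head = list(variant = cfg$seg_head_variant,
                            classes = cfg$seg_classes,
                            tap_layer = cfg$seg_tap_layer,
                            tap_channels = cfg$seg_tap_channels))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname model_config_to_yaml
#' @export
model_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  model_config(num_classes = y$nc, img_size = y$img_size,
               depth_multiple = y$depth_multiple,
               width_multiple = y$width_multiple,
               anchors = lapply(y$anchors, function(a)
                 matrix(a, ncol = 2, byrow = TRUE)),
               seg_head_variant = y$seg_head$variant,
               seg_classes = y$seg_head$classes,
               activation = y$activation,
               seg_tap_layer = y$seg_head$tap_layer,
               seg_tap_channels = y$seg_head$tap_channels)
}
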