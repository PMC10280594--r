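# Training loop, evaluation report, ablation harness and the command-style
# entry points the shell script wraps.

#' Training configuration
#'
#' Defaults follow the published recipe: 640 px inputs, SGD with initial
#' learning rate 0.0015, batch size 2, 300 epochs, HSV gains
#' (0.015, 0.7, 0.4), tricks of the winning ablation group (HSV + mosaic),
#' GhostC3 segmentation head and HardSwish activations. The `desk`
#' profile is a CPU-scale variant (160 px, width 0.25) used for smoke
#' runs and the learning-sanity gate.
#'
#' @param img_size input size, divisible by 32.
#' @param epochs training epochs (full passes over the train split).
#' @param batch_size images per step.
#' @param optimizer `"SGD"` (momentum) or `"Adam"`.
#' @param lr0 initial learning rate.
#' @param momentum SGD momentum.
#' @param tricks augmentation/loss switches, subset of
#'   `c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp", "Fliplrud")`.
#' @param seg_head `"C3"`, `"GhostC3"` or `"none"`.
#' @param activation `"Swish"` or `"HardSwish"`.
#' @param width_multiple,depth_multiple model scaling.
#' @param det_weight,seg_weight multitask loss weights.
#' @param fl_gamma focal focusing parameter used when `"FocalLoss"` is in
#'   `tricks`.
#' @param seed global seed governing weight init, augmentation and data
#'   order.
#' @param profile `"paper"` or `"desk"`; `"desk"` overrides `img_size`,
#'   `width_multiple`, `batch_size` and `lr0` with CPU-scale values.
#' @return object of class `fishseg_train_config`.
#' @export
train_config <- function(img_size = 640, epochs = 300, batch_size = 2,
                         optimizer = c("SGD", "Adam"), lr0 = 0.0015,
                         momentum = 0.937,
                         tricks = c("HSV_Aug", "Mosaic"),
                         seg_head = c("GhostC3", "C3", "none"),
                         activation = c("HardSwish", "Swish"),
                         width_multiple = 0.50, depth_multiple = 0.33,
                         det_weight = 1, seg_weight = 1,
                         fl_gamma = 1.5, seed = 0,
                         profile = c("paper", "desk")) {
  optimizer <- match.arg(optimizer)
  seg_head <- match.arg(seg_head)
  activation <- match.arg(activation)
  profile <- match.arg(profile)
  if (profile == "desk") {
    img_size <- 160L; width_multiple <- 0.25; batch_size <- 4L; lr0 <- 0.02
  }
  stopifnot(epochs >= 1, img_size %% 32 == 0)
  # validates trick combination rules (MixUp needs Mosaic)
  aug <- augment_config(tricks = tricks, seed = seed)
  structure(list(img_size = as.integer(img_size), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 lr0 = lr0, momentum = momentum, tricks = tricks,
                 seg_head = seg_head, activation = activation,
                 width_multiple = width_multiple,
                 depth_multiple = depth_multiple,
                 det_weight = det_weight, seg_weight = seg_weight,
                 fl_gamma = fl_gamma, seed = as.integer(seed),
                 augment = aug, profile = profile),
            class = "fishseg_train_config")
}

samples_to_batch <- function(samples, img_size) {
  N <- length(samples)
  x <- array(0, c(img_size, img_size, 3L, N))
  masks <- array(0, c(img_size, img_size, N))
  targets <- NULL
  has_mask <- logical(N)
  for (i in seq_len(N)) {
    s <- samples[[i]]
    stopifnot(all(dim(s$image)[1:2] == img_size))
    x[, , , i] <- s$image / 255
    if (!is.null(s$mask)) { masks[, , i] <- s$mask; has_mask[i] <- TRUE }
    if (nrow(s$boxes))
      targets <- rbind(targets, cbind(img = i, cls = s$boxes$class,
                                      x = s$boxes$cx, y = s$boxes$cy,
                                      w = s$boxes$w, h = s$boxes$h))
  }
  list(x = x, targets = targets, masks = masks, has_mask = has_mask)
}

train_step <- function(model, batch, hyp, weights = c(det = 1, seg = 1),
                       lr = 0.01, momentum = 0.937) {
  fwd <- forward_graph(model, batch$x, train = TRUE)
  dl <- detection_loss(model, fwd$det, batch$targets, hyp)
  grads_out <- list()
  for (s in seq_along(fwd$det))
    grads_out[[as.character(model$det_nodes[s])]] <-
      dl$grads[[s]] * weights[[1]]
  seg_l <- 0
  if (!is.null(fwd$seg) && any(batch$has_mask) && weights[[2]] > 0) {
    sl <- seg_loss_and_grad(fwd$seg, batch$masks, weights[[2]])
    seg_l <- sl$loss
    grads_out[[as.character(model$seg_node)]] <- sl$grad
  }
  wg <- backward_graph(model, fwd, grads_out)
  model <- apply_bn_updates(model, fwd$bn_updates)
  model <- sgd_step(model, wg, lr = lr, momentum = momentum)
  loss <- multitask_loss(dl$box, dl$objectness, dl$classification,
                         seg_l / max(weights[[2]], 1e-12), weights)
  list(model = model, loss = loss)
}

#' Train the multitask model
#'
#' Runs the configured number of epochs of momentum SGD over a dataset
#' (either a directory in the layout written by [render_dataset()] or an
#' in-memory list of samples), applying the configured augmentation
#' pipeline, and logs one structured record per epoch. Samples without
#' masks contribute only to the detection loss.
#'
#' @param cfg a [train_config()].
#' @param dataset dataset directory, or `NULL` when `samples` is given.
#' @param samples optional list of [image_sample()]s used directly.
#' @param max_steps optional hard cap on total optimiser steps.
#' @param log_file optional path for JSON-line epoch logs.
#' @param verbose print per-epoch summaries.
#' @return list (class `fishseg_run`) with the trained `model`, the config
#'   snapshot, per-epoch `history` and the final training-set `report`.
#' @export
cmd_train <- function(cfg, dataset = NULL, samples = NULL, max_steps = Inf,
                      log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "fishseg_train_config"))
  if (is.null(samples)) {
    if (is.null(dataset)) stop("provide `dataset` or `samples`")
    samples <- load_dataset(dataset, "train")
  }
  if (!length(samples)) stop("empty training set")
  set.seed(cfg$seed)
  mcfg <- model_config(num_classes = 1, img_size = cfg$img_size,
                       depth_multiple = cfg$depth_multiple,
                       width_multiple = cfg$width_multiple,
                       seg_head_variant = cfg$seg_head,
                       activation = cfg$activation)
  model <- build_model(mcfg, seed = cfg$seed)
  hyp <- det_hyp(fl_gamma = if ("FocalLoss" %in% cfg$tricks) cfg$fl_gamma else 0)
  weights <- c(det = cfg$det_weight, seg = cfg$seg_weight)
  rng <- rng_stream(cfg$seed + 1L)
  aug_on <- length(augment_plan(cfg$augment)) > 0
  history <- list()
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_rng(rng, sample.int(length(samples)))
    ep_loss <- NULL
    for (at in seq(1, length(ord), by = cfg$batch_size)) {
      if (step >= max_steps) break
      idx <- ord[at:min(at + cfg$batch_size - 1L, length(ord))]
      bs <- lapply(samples[idx], function(s) {
        if (aug_on) augment_pipeline(s, samples, cfg$augment, rng) else s
      })
      batch <- samples_to_batch(bs, cfg$img_size)
      st <- train_step(model, batch, hyp, weights, lr = cfg$lr0,
                       momentum = cfg$momentum)
      model <- st$model
      step <- step + 1L
      ep_loss <- rbind(ep_loss, unlist(st$loss[c("box", "objectness",
                                                 "classification",
                                                 "segmentation", "total")]))
    }
    rec <- as.list(colMeans(ep_loss))
    rec$epoch <- ep; rec$steps <- step
    history[[ep]] <- rec
    if (!is.null(log_file))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_file,
          append = TRUE)
    if (verbose)
      cat(sprintf("epoch %3d  total %.4f (box %.4f obj %.4f seg %.4f)\n",
                  ep, rec$total, rec$box, rec$objectness, rec$segmentation))
    if (step >= max_steps) break
  }
  report <- cmd_evaluate(model, samples, conf_thr = 0.25)
  structure(list(model = model, config = cfg, history = history,
                 report = report), class = "fishseg_run")
}

#' Evaluate a model on a set of samples
#'
#' Computes the fixed-threshold detection metrics (precision, recall, F1
#' at `conf_thr`), the curve metrics (mAP@0.5 and mAP@0.5:0.95 from a
#' low-threshold decode), and the segmentation metrics (pixel accuracy,
#' mIoU).
#'
#' @param model a trained `fishseg_model` (or a `fishseg_run`).
#' @param samples list of [image_sample()]s with ground truth.
#' @param conf_thr confidence threshold for the tabled P/R/F1.
#' @param iou_nms NMS suppression threshold.
#' @return object of class `fishseg_report`.
#' @export
cmd_evaluate <- function(model, samples, conf_thr = 0.25, iou_nms = 0.45) {
  if (inherits(model, "fishseg_run")) model <- model$model
  if (!length(samples)) stop("empty evaluation split")
  S <- model$cfg$img_size
  gts <- lapply(samples, function(s) {
    if (!nrow(s$boxes)) return(matrix(numeric(0), 0, 5))
    cbind((s$boxes$cx - s$boxes$w / 2) * S, (s$boxes$cy - s$boxes$h / 2) * S,
          (s$boxes$cx + s$boxes$w / 2) * S, (s$boxes$cy + s$boxes$h / 2) * S,
          s$boxes$class)
  })
  dets_lo <- vector("list", length(samples))
  seg_counts <- confusion_counts()
  per_class <- NULL
  for (i in seq_along(samples)) {
    batch <- samples_to_batch(samples[i], S)
    out <- forward(model, batch$x, train_mode = FALSE)
    dets_lo[[i]] <- decode_and_nms(model, out, conf_thr = 0.001,
                                   iou_thr = iou_nms)[[1]]
    if (!is.null(out$seg_logits) && !is.null(samples[[i]]$mask)) {
      pred <- matrix(as.integer(out$seg_logits[1, 2, , ] > 0), S, S)
      cc <- seg_confusion(pred, samples[[i]]$mask, 2)
      per_class <- if (is.null(per_class)) cc else
        mapply(function(a, b) confusion_counts(a$tp + b$tp, a$fp + b$fp,
                                               a$fn + b$fn, a$tn + b$tn),
               per_class, cc, SIMPLIFY = FALSE)
    }
  }
  cm <- confusion_counts()
  for (i in seq_along(samples)) {
    d <- dets_lo[[i]]
    d <- d[d$confidence >= conf_thr, , drop = FALSE]
    m <- match_detections(d[, c("x1", "y1", "x2", "y2", "confidence")],
                          gts[[i]][, 1:4, drop = FALSE], 0.5)
    cm <- confusion_counts(cm$tp + m$counts$tp, cm$fp + m$counts$fp,
                           cm$fn + m$counts$fn)
  }
  prf <- precision_recall_f1(cm)
  map50 <- map_at(dets_lo, gts, 0.5)
  map5095 <- map_at(dets_lo, gts, seq(0.5, 0.95, by = 0.05))
  seg_acc_v <- if (!is.null(per_class)) seg_acc(per_class[[2]]) else NA_real_
  miou_v <- if (!is.null(per_class)) miou(per_class) else NA_real_
  structure(list(precision = unname(prf["precision"]),
                 recall = unname(prf["recall"]), f1 = unname(prf["f1"]),
                 map50 = map50, map5095 = map5095,
                 seg_acc = seg_acc_v, seg_miou = miou_v,
                 conf_thr = conf_thr, n_images = length(samples)),
            class = "fishseg_report")
}

#' @export
print.fishseg_report <- function(x, ...) {
  cat(sprintf("Precision  Recall  F1-score  mAP@0.5  Seg Acc  Seg mIoU  (conf %.2f, n=%d)\n",
              x$conf_thr, x$n_images))
  cat(sprintf("%9.3f  %6.3f  %8.3f  %7.3f  %7.3f  %8.3f\n",
              x$precision, x$recall, x$f1, x$map50,
              ifelse(is.na(x$seg_acc), NaN, x$seg_acc),
              ifelse(is.na(x$seg_miou), NaN, x$seg_miou)))
  invisible(x)
}

#' The twelve published ablation groups
#'
#' The trick combinations explored in the augmentation ablation, honouring
#' the dependency that MixUp is only used when mosaic is enabled. Group 8
#' (HSV + mosaic) is the winning configuration.
#'
#' @return named list of character vectors.
#' @export
ablation_groups <- function() {
  list(
    g1 = character(0),
    g2 = "HSV_Aug",
    g3 = c("HSV_Aug", "FocalLoss"),
    g4 = c("HSV_Aug", "FocalLoss", "Mosaic"),
    g5 = c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp"),
    g6 = c("HSV_Aug", "FocalLoss", "Fliplrud"),
    g7 = c("HSV_Aug", "FocalLoss", "Mosaic", "Fliplrud"),
    g8 = c("HSV_Aug", "Mosaic"),
    g9 = c("HSV_Aug", "Mosaic", "MixUp"),
    g10 = c("HSV_Aug", "Mosaic", "Fliplrud"),
    g11 = c("HSV_Aug", "Mosaic", "MixUp", "Fliplrud"),
    g12 = c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp", "Fliplrud"))
}

#' Ablation harness
#'
#' Validates and schedules a set of trick groups under a shared seed and,
#' unless `dry_run`, trains and evaluates each. Groups using MixUp without
#' mosaic are rejected up front.
#'
#' @param groups named list of trick sets (default: the published twelve).
#' @param base_cfg the shared [train_config()] template.
#' @param dataset,samples training data, as in [cmd_train()].
#' @param dry_run only validate and return the schedule.
#' @param max_steps per-group step cap when running.
#' @return data frame: the schedule (dry run) or the comparison grid with
#'   metric columns.
#' @export
cmd_ablate <- function(groups = ablation_groups(),
                       base_cfg = train_config(profile = "desk"),
                       dataset = NULL, samples = NULL, dry_run = FALSE,
                       max_steps = 60) {
  all_tricks <- c("HSV_Aug", "FocalLoss", "Mosaic", "MixUp", "Fliplrud")
  for (nm in names(groups)) {
    gr <- groups[[nm]]
    if ("MixUp" %in% gr && !"Mosaic" %in% gr)
      stop("config error in ", nm,
           ": MixUp is only used as the Mosaic strategy is enabled")
    if (!all(gr %in% all_tricks))
      stop("config error in ", nm, ": unknown trick")
  }
  sched <- data.frame(group = names(groups))
  for (tk in all_tricks)
    sched[[tk]] <- vapply(groups, function(g) tk %in% g, logical(1))
  if (dry_run) return(sched)
  rows <- NULL
  for (nm in names(groups)) {
    cfg <- base_cfg
    cfg$tricks <- groups[[nm]]
    cfg$augment <- augment_config(tricks = groups[[nm]], seed = cfg$seed)
    run <- cmd_train(cfg, dataset = dataset, samples = samples,
                     max_steps = max_steps)
    r <- run$report
    rows <- rbind(rows, data.frame(group = nm, precision = r$precision,
                                   recall = r$recall, f1 = r$f1,
                                   map50 = r$map50, seg_acc = r$seg_acc,
                                   seg_miou = r$seg_miou))
  }
  merge(sched, rows, by = "group", sort = FALSE)
}

#' Parameter-count command
#'
#' @param variant segmentation head variant (`"c3"`, `"ghostc3"`,
#'   `"none"`).
#' @param num_classes detection classes.
#' @return list with `total` and the per-module `table`.
#' @export
cmd_count_params <- function(variant = c("ghostc3", "c3", "none"),
                             num_classes = 1) {
  variant <- match.arg(tolower(variant), c("ghostc3", "c3", "none"))
  head <- c(ghostc3 = "GhostC3", c3 = "C3", none = "none")[[variant]]
  m <- build_model(model_config(num_classes = num_classes,
                                seg_head_variant = head), seed = 0)
  list(total = count_parameters(m), table = param_table(m))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a format version field.
#'
#' @param model a `fishseg_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, cfg = model$cfg,
               weights = lapply(model$nodes, `[[`, "weights")), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L)
    stop("unsupported checkpoint version")
  model <- build_model(ck$cfg, seed = 0)
  for (i in seq_along(model$nodes)) model$nodes[[i]]$weights <- ck$weights[[i]]
  model
}
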