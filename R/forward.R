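# Graph execution. A model is a topologically ordered list of primitive
# nodes; forward caches whatever each node's backward needs (batch-norm
# statistics, pooling argmax indices, pre-activation maps), and backward
# walks the list in reverse accumulating gradients for inputs and weights.
# Feature tensors are (H, W, C, N) arrays throughout.

act_code <- function(act) switch(act, None = 0L, Swish = 1L, HardSwish = 2L,
                                 stop("unknown activation ", act))

concat_channels <- function(mats) {
  d <- dim(mats[[1]])
  cs <- vapply(mats, function(m) dim(m)[3], integer(1))
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (m in mats) {
    cm <- dim(m)[3]
    y[, , at + seq_len(cm), ] <- m
    at <- at + cm
  }
  y
}

forward_graph <- function(model, x, train = FALSE, bn_momentum = 0.03) {
  nodes <- model$nodes
  outs <- vector("list", length(nodes))
  caches <- if (train) vector("list", length(nodes)) else NULL
  bn_updates <- if (train) list() else NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    w <- nd$weights
    inp <- if (length(nd$from) && nd$from[1] > 0L) outs[[nd$from[1]]] else x
    outs[[i]] <- switch(nd$op,
      input = x,
      cbs = {
        z <- cpp_conv2d_fw(inp, w$W, NULL, nd$k, nd$s, nd$k %/% 2L)
        if (train) {
          bn <- cpp_bn_fw_train(z, w$gamma, w$beta, 1e-5)
          caches[[i]] <- list(xhat = bn$xhat, invstd = bn$invstd,
                              bnout = bn$y)
          bn_updates[[length(bn_updates) + 1L]] <-
            list(node = i, mean = bn$mean, var = bn$var)
          cpp_act_fw(bn$y, act_code(nd$act))
        } else {
          z <- cpp_bn_fw_eval(z, w$gamma, w$beta, w$rm, w$rv, 1e-5)
          cpp_act_fw(z, act_code(nd$act))
        }
      },
      dwcbs = {
        z <- cpp_dwconv_fw(inp, w$W, nd$k, nd$s, nd$k %/% 2L)
        if (train) {
          bn <- cpp_bn_fw_train(z, w$gamma, w$beta, 1e-5)
          caches[[i]] <- list(xhat = bn$xhat, invstd = bn$invstd,
                              bnout = bn$y)
          bn_updates[[length(bn_updates) + 1L]] <-
            list(node = i, mean = bn$mean, var = bn$var)
          cpp_act_fw(bn$y, act_code(nd$act))
        } else {
          z <- cpp_bn_fw_eval(z, w$gamma, w$beta, w$rm, w$rv, 1e-5)
          cpp_act_fw(z, act_code(nd$act))
        }
      },
      conv = cpp_conv2d_fw(inp, w$W, w$b, nd$k, nd$s, nd$k %/% 2L),
      maxpool = {
        mp <- cpp_maxpool_fw(inp, nd$k)
        if (train) caches[[i]] <- list(idx = mp$idx)
        mp$y
      },
      up_nearest2 = cpp_up_nearest2_fw(inp),
      up_bilinear2 = cpp_bilinear_fw(inp, 2L * dim(inp)[1], 2L * dim(inp)[2],
                                     FALSE),
      focus_slice = cpp_focus_fw(inp),
      concat = concat_channels(outs[nd$from]),
      add = outs[[nd$from[1]]] + outs[[nd$from[2]]],
      stop("unknown op ", nd$op))
  }
  list(outs = outs, caches = caches, bn_updates = bn_updates,
       det = outs[model$det_nodes],
       seg = if (!is.na(model$seg_node)) outs[[model$seg_node]] else NULL)
}

# grads_out: list mapping node index -> gradient array of that node's output.
# Returns per-node weight gradients (indices into model$nodes).
backward_graph <- function(model, fwd, grads_out) {
  nodes <- model$nodes
  n <- length(nodes)
  grads <- vector("list", n)
  wgrads <- vector("list", n)
  for (i in names(grads_out)) grads[[as.integer(i)]] <- grads_out[[i]]
  acc <- function(j, g) {
    if (j <= 0L) return(invisible(NULL))
    grads[[j]] <<- if (is.null(grads[[j]])) g else grads[[j]] + g
    invisible(NULL)
  }
  for (i in n:1) {
    dy <- grads[[i]]
    if (is.null(dy)) next
    nd <- nodes[[i]]
    w <- nd$weights
    from <- nd$from
    inp <- if (length(from) && from[1] > 0L) fwd$outs[[from[1]]] else NULL
    switch(nd$op,
      input = NULL,
      cbs = {
        ca <- fwd$caches[[i]]
        dbn <- cpp_act_bw(ca$bnout, dy, act_code(nd$act))
        bw <- cpp_bn_bw(dbn, ca$xhat, ca$invstd, w$gamma)
        need_dx <- nodes[[from[1]]]$op != "input"
        cv <- cpp_conv2d_bw(inp, w$W, bw$dx, nd$k, nd$s, nd$k %/% 2L,
                            need_dx, FALSE)
        wgrads[[i]] <- list(W = cv$dw, gamma = bw$dgamma, beta = bw$dbeta)
        if (need_dx) acc(from[1], cv$dx)
      },
      dwcbs = {
        ca <- fwd$caches[[i]]
        dbn <- cpp_act_bw(ca$bnout, dy, act_code(nd$act))
        bw <- cpp_bn_bw(dbn, ca$xhat, ca$invstd, w$gamma)
        cv <- cpp_dwconv_bw(inp, w$W, bw$dx, nd$k, nd$s, nd$k %/% 2L, TRUE)
        wgrads[[i]] <- list(W = cv$dw, gamma = bw$dgamma, beta = bw$dbeta)
        acc(from[1], cv$dx)
      },
      conv = {
        cv <- cpp_conv2d_bw(inp, w$W, dy, nd$k, nd$s, nd$k %/% 2L, TRUE, TRUE)
        wgrads[[i]] <- list(W = cv$dw, b = cv$db)
        acc(from[1], cv$dx)
      },
      maxpool = acc(from[1], cpp_maxpool_bw(dy, fwd$caches[[i]]$idx)),
      up_nearest2 = acc(from[1], cpp_up_nearest2_bw(dy)),
      up_bilinear2 = {
        d <- dim(fwd$outs[[from[1]]])
        acc(from[1], cpp_bilinear_bw(dy, d[1], d[2], FALSE))
      },
      focus_slice = {
        d <- dim(fwd$outs[[from[1]]])
        acc(from[1], cpp_focus_bw(dy, d[1], d[2]))
      },
      concat = {
        at <- 0L
        for (f in from) {
          cf <- dim(fwd$outs[[f]])[3]
          acc(f, dy[, , at + seq_len(cf), , drop = FALSE])
          at <- at + cf
        }
      },
      add = { acc(from[1], dy); acc(from[2], dy) },
      stop("unknown op ", nd$op))
    grads[[i]] <- NULL   # free
  }
  wgrads
}

apply_bn_updates <- function(model, bn_updates, momentum = 0.03) {
  for (u in bn_updates) {
    w <- model$nodes[[u$node]]$weights
    model$nodes[[u$node]]$weights$rm <- (1 - momentum) * w$rm + momentum * u$mean
    model$nodes[[u$node]]$weights$rv <- (1 - momentum) * w$rv + momentum * u$var
  }
  model
}

sgd_step <- function(model, wgrads, lr, momentum = 0.937,
                     weight_decay = 0) {
  if (is.null(model$opt)) model$opt <- list()
  for (i in seq_along(wgrads)) {
    gw <- wgrads[[i]]
    if (is.null(gw)) next
    key <- as.character(i)
    v <- model$opt[[key]]
    if (is.null(v)) v <- lapply(gw, function(g) g * 0)
    w <- model$nodes[[i]]$weights
    for (nm in names(gw)) {
      g <- gw[[nm]]
      if (weight_decay > 0 && nm == "W") g <- g + weight_decay * w[[nm]]
      v[[nm]] <- momentum * v[[nm]] + g
      w[[nm]] <- w[[nm]] - lr * v[[nm]]
    }
    model$opt[[key]] <- v
    model$nodes[[i]]$weights <- w
  }
  model
}

#' Run the multitask network
#'
#' Executes one forward pass of the shared backbone and both heads.
#'
#' @param model a `fishseg_model`.
#' @param batch numeric array `(N, 3, H, W)` with values in `[0, 1]`, or
#'   `(H, W, 3, N)` (the internal layout); `H = W = cfg$img_size`.
#' @param train_mode use batch statistics in normalisation layers (the
#'   evaluation path uses running statistics and is deterministic).
#' @return list with `det_maps` (three arrays `(N, 3, H/s, W/s, 5 + nc)`
#'   for strides 8, 16, 32) and `seg_logits`
#'   (`(N, seg_classes, H, W)`; channel 1 is the constant background logit,
#'   channel 2 the fish logit, so the softmax over channels equals the
#'   sigmoid of the fish logit).
#' @export
forward <- function(model, batch, train_mode = FALSE) {
  d <- dim(batch)
  if (length(d) != 4) stop("shape error: batch must be a 4-d array")
  if (d[2] == 3L && d[1] != d[4]) {            # (N, 3, H, W) -> (H, W, 3, N)
    batch <- aperm(batch, c(3, 4, 2, 1))
    d <- dim(batch)
  }
  if (d[3] != 3L) stop("shape error: expected 3 colour channels")
  if (d[1] != model$cfg$img_size || d[2] != model$cfg$img_size)
    stop("shape error: input must be ", model$cfg$img_size, " x ",
         model$cfg$img_size)
  fwd <- forward_graph(model, batch, train = train_mode)
  nc <- model$cfg$num_classes
  no <- 5L + nc
  det_maps <- lapply(fwd$det, function(m) {
    dd <- dim(m)
    dim(m) <- c(dd[1], dd[2], no, 3L, dd[4])
    aperm(m, c(5, 4, 1, 2, 3))
  })
  seg_logits <- NULL
  if (!is.null(fwd$seg)) {
    z <- aperm(fwd$seg, c(4, 3, 1, 2))   # (N, 1, H, W)
    seg_logits <- array(0, c(dim(z)[1], 2L, dim(z)[3], dim(z)[4]))
    seg_logits[, 2L, , ] <- z
  }
  list(det_maps = det_maps, seg_logits = seg_logits)
}
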