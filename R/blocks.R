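# Building blocks are described as small DAGs of primitive layers. The same
# node lists drive closed-form parameter counting and, in model.R, the
# instantiation of trainable weights. Node "from" indices refer to earlier
# nodes in the same graph environment; by convention the caller passes the
# index of the block's input node.
#
# Primitive ops:
#   cbs     conv (no bias) + batch-norm + activation   params c1*c2*k^2 + 2*c2
#   dwcbs   depthwise conv + batch-norm + activation   params c*k^2    + 2*c
#   conv    plain conv with bias (detect / projection) params c1*c2*k^2 + c2
#   maxpool / up_nearest2 / up_bilinear2 / focus_slice / concat / add: 0

graph_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

graph_add <- function(g, op, from, ...) {
  g$nodes[[length(g$nodes) + 1L]] <- c(list(op = op, from = as.integer(from)),
                                       list(...))
  length(g$nodes)
}

prim_params <- function(node) {
  switch(node$op,
    cbs    = node$c1 * node$c2 * node$k^2 + 2L * node$c2,
    dwcbs  = node$c * node$k^2 + 2L * node$c,
    conv   = node$c1 * node$c2 * node$k^2 + node$c2,
    0L)
}

graph_params <- function(nodes) sum(vapply(nodes, prim_params, numeric(1)))

check_pos <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1 || x < 1 || x != as.integer(x))
    stop("`", nm, "` must be a positive integer")
  as.integer(x)
}

check_ks <- function(k, s) {
  if (k %% 2 != 1) stop("kernel size `k` must be odd")
  if (!s %in% c(1L, 2L)) stop("stride `s` must be 1 or 2")
}

# ---- graph builders (return index of the block's output node) --------------

build_cbs <- function(g, inp, c1, c2, k = 1L, s = 1L, act = "Swish") {
  graph_add(g, "cbs", inp, c1 = c1, c2 = c2, k = k, s = s, act = act)
}

build_focus <- function(g, inp, c1, c2, k = 3L, act = "Swish") {
  sl <- graph_add(g, "focus_slice", inp, c1 = c1, c2 = 4L * c1)
  build_cbs(g, sl, 4L * c1, c2, k, 1L, act)
}

build_spp <- function(g, inp, c1, c2, pool_kernels = c(1L, 5L, 9L, 13L),
                      act = "Swish") {
  c_ <- c1 %/% 2L
  cv1 <- build_cbs(g, inp, c1, c_, 1L, 1L, act)
  branches <- vapply(pool_kernels, function(k) {
    if (k == 1L) cv1 else graph_add(g, "maxpool", cv1, k = as.integer(k), c = c_)
  }, integer(1))
  cat_ <- graph_add(g, "concat", branches)
  build_cbs(g, cat_, c_ * length(branches), c2, 1L, 1L, act)
}

build_bottleneck <- function(g, inp, c1, c2, shortcut = TRUE, act = "Swish") {
  # inner expansion e = 1.0, the convention inside C3 blocks
  cv1 <- build_cbs(g, inp, c1, c2, 1L, 1L, act)
  cv2 <- build_cbs(g, cv1, c2, c2, 3L, 1L, act)
  if (shortcut && c1 == c2) graph_add(g, "add", c(inp, cv2)) else cv2
}

build_c3 <- function(g, inp, c1, c2, n = 1L, shortcut = TRUE, act = "Swish") {
  c_ <- c2 %/% 2L
  cv1 <- build_cbs(g, inp, c1, c_, 1L, 1L, act)
  cv2 <- build_cbs(g, inp, c1, c_, 1L, 1L, act)
  m <- cv1
  for (i in seq_len(n)) m <- build_bottleneck(g, m, c_, c_, shortcut, act)
  cat_ <- graph_add(g, "concat", c(m, cv2))
  build_cbs(g, cat_, 2L * c_, c2, 1L, 1L, act)
}

build_ghostconv <- function(g, inp, c1, c2, k = 1L, s = 1L, act = "Swish") {
  c_ <- c2 %/% 2L
  primary <- build_cbs(g, inp, c1, c_, k, s, act)
  cheap <- graph_add(g, "dwcbs", primary, c = c_, k = 5L, s = 1L, act = act)
  graph_add(g, "concat", c(primary, cheap))
}

build_ghostbottleneck <- function(g, inp, c1, c2, stride = 1L,
                                  act = "Swish") {
  c_ <- c2 %/% 2L
  if (stride == 1L) {
    gc1 <- build_ghostconv(g, inp, c1, c_, 1L, 1L, act)
    gc2 <- build_ghostconv(g, gc1, c_, c2, 1L, 1L, "None")
    graph_add(g, "add", c(inp, gc2))
  } else {
    gc1 <- build_ghostconv(g, inp, c1, c_, 1L, 1L, act)
    dw <- graph_add(g, "dwcbs", gc1, c = c_, k = 3L, s = 2L, act = "None")
    gc2 <- build_ghostconv(g, dw, c_, c2, 1L, 1L, "None")
    sdw <- graph_add(g, "dwcbs", inp, c = c1, k = 3L, s = 2L, act = "None")
    spw <- build_cbs(g, sdw, c1, c2, 1L, 1L, "None")
    graph_add(g, "add", c(gc2, spw))
  }
}

build_ghostc3 <- function(g, inp, c1, c2, n = 1L, act = "Swish") {
  c_ <- c2 %/% 2L
  cv1 <- build_cbs(g, inp, c1, c_, 1L, 1L, act)
  cv2 <- build_cbs(g, inp, c1, c_, 1L, 1L, act)
  m <- cv1
  for (i in seq_len(n)) m <- build_ghostbottleneck(g, m, c_, c_, 1L, act)
  cat_ <- graph_add(g, "concat", c(m, cv2))
  build_cbs(g, cat_, 2L * c_, c2, 1L, 1L, act)
}

# ---- public block specs -----------------------------------------------------

new_block_spec <- function(kind, g, out, fields) {
  structure(c(list(kind = kind, graph = g$nodes, out = out,
                   n_params = graph_params(g$nodes)), fields),
            class = "fishseg_block_spec")
}

#' @export
print.fishseg_block_spec <- function(x, ...) {
  cat(sprintf("<%s block: %s parameters, %d primitive layers>\n",
              x$kind, format(x$n_params, big.mark = ","), length(x$graph)))
  invisible(x)
}

#' Number of trainable parameters of a block specification
#'
#' Closed-form count over the block's primitive layers: convolutions carry
#' no bias (batch normalisation absorbs it) and contribute
#' `c1 * c2 * k^2`; each batch-normalised channel adds a scale and a shift;
#' plain convolutions (detection / projection layers) add one bias per
#' output channel.
#'
#' @param spec a `fishseg_block_spec`.
#' @return integer parameter count.
#' @export
block_params <- function(spec) {
  stopifnot(inherits(spec, "fishseg_block_spec"))
  spec$n_params
}

#' Convolution + batch-norm + activation (CBS) block specification
#'
#' @param c1,c2 input / output channel counts.
#' @param k odd kernel size in pixels.
#' @param s stride, 1 or 2.
#' @param activation `"Swish"`, `"HardSwish"` or `"None"`.
#' @return a `fishseg_block_spec`.
#' @export
cbs_spec <- function(c1, c2, k = 1, s = 1, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2"); check_ks(k, s)
  g <- graph_new()
  out <- build_cbs(g, 0L, c1, c2, as.integer(k), as.integer(s), activation)
  new_block_spec("CBS", g, out, list(c1 = c1, c2 = c2, k = as.integer(k),
                                     s = as.integer(s), activation = activation))
}

#' Focus (space-to-depth) stem specification
#'
#' Slices the input into four half-resolution interleaves, concatenates
#' them channel-wise (4 x c1) and applies a CBS block: a lossless 2x
#' downsampling stem.
#'
#' @inheritParams cbs_spec
#' @return a `fishseg_block_spec`.
#' @export
focus_spec <- function(c1, c2, k = 3, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2"); check_ks(k, 1L)
  g <- graph_new()
  out <- build_focus(g, 0L, c1, c2, as.integer(k), activation)
  new_block_spec("Focus", g, out, list(c1 = c1, c2 = c2, k = as.integer(k),
                                       activation = activation))
}

#' Spatial pyramid pooling (SPP) block specification
#'
#' Parallel stride-1 max pooling at several odd kernel sizes (kernel 1 is
#' the identity branch), concatenated and fused by a 1x1 CBS.
#'
#' @inheritParams cbs_spec
#' @param pool_kernels odd pooling kernel sizes.
#' @return a `fishseg_block_spec`.
#' @export
spp_spec <- function(c1, c2, pool_kernels = c(1, 5, 9, 13),
                     activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2")
  if (any(pool_kernels %% 2 != 1)) stop("`pool_kernels` must be odd")
  g <- graph_new()
  out <- build_spp(g, 0L, c1, c2, as.integer(pool_kernels), activation)
  new_block_spec("SPP", g, out, list(c1 = c1, c2 = c2,
                                     pool_kernels = as.integer(pool_kernels),
                                     activation = activation))
}

#' C3 (cross-stage-partial) block specification
#'
#' Two 1x1-reduced branches; one passes through `n` stacked residual
#' bottlenecks (1x1 then 3x3 convolution), the branches are concatenated
#' and fused by a 1x1 CBS.
#'
#' @inheritParams cbs_spec
#' @param n number of inner bottleneck units, `>= 1`.
#' @param shortcut use residual connections inside the bottlenecks.
#' @return a `fishseg_block_spec`.
#' @export
c3_spec <- function(c1, c2, n = 1, shortcut = TRUE, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2")
  if (n < 1) stop("invalid block spec: `n` must be >= 1")
  g <- graph_new()
  out <- build_c3(g, 0L, c1, c2, as.integer(n), shortcut, activation)
  new_block_spec("C3", g, out, list(c1 = c1, c2 = c2, n = as.integer(n),
                                    shortcut = shortcut, activation = activation))
}

#' Ghost convolution specification
#'
#' Produces half the output channels with a regular `k` x `k` convolution
#' (the primary path) and the other half with a cheap 5x5 depthwise
#' convolution applied to the primary output; the two halves are
#' concatenated. Parameter count:
#' `c1*(c2/2)*k^2 + 2*(c2/2) + (c2/2)*25 + 2*(c2/2)`.
#'
#' @inheritParams cbs_spec
#' @return a `fishseg_block_spec`.
#' @export
ghostconv_spec <- function(c1, c2, k = 1, s = 1, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2"); check_ks(k, s)
  if (c2 %% 2 != 0)
    stop("invalid block spec: GhostConv requires an even `c2` ",
         "(half primary, half cheap)")
  g <- graph_new()
  out <- build_ghostconv(g, 0L, c1, c2, as.integer(k), as.integer(s),
                         activation)
  new_block_spec("GhostConv", g, out,
                 list(c1 = c1, c2 = c2, k = as.integer(k), s = as.integer(s),
                      activation = activation))
}

#' Ghost bottleneck specification
#'
#' Stride 1: two stacked 1x1 Ghost convolutions with an identity residual
#' connection (requires `c1 == c2`). Stride 2: a 3x3 depthwise
#' downsampling between the Ghost convolutions, with a parallel
#' depthwise-downsample + 1x1 convolution shortcut.
#'
#' @inheritParams cbs_spec
#' @param stride 1 or 2.
#' @return a `fishseg_block_spec`.
#' @export
ghostbottleneck_spec <- function(c1, c2, stride = 1, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2")
  if (!stride %in% c(1, 2))
    stop("invalid block spec: GhostBottleneck stride must be 1 or 2")
  if (stride == 1 && c1 != c2)
    stop("invalid block spec: the stride-1 identity residual requires c1 == c2")
  if (c2 %% 2 != 0) stop("invalid block spec: `c2` must be even")
  g <- graph_new()
  out <- build_ghostbottleneck(g, 0L, c1, c2, as.integer(stride), activation)
  new_block_spec("GhostBottleneck", g, out,
                 list(c1 = c1, c2 = c2, s = as.integer(stride),
                      activation = activation))
}

#' GhostC3 block specification
#'
#' The C3 topology with every inner bottleneck replaced by a stride-1
#' Ghost bottleneck; the outer 1x1 branch/fuse convolutions are unchanged.
#' Always uses strictly fewer parameters than the C3 block with the same
#' `c1`, `c2`, `n`.
#'
#' @inheritParams c3_spec
#' @return a `fishseg_block_spec`.
#' @export
ghostc3_spec <- function(c1, c2, n = 1, activation = "Swish") {
  c1 <- check_pos(c1, "c1"); c2 <- check_pos(c2, "c2")
  if (n < 1) stop("invalid block spec: `n` must be >= 1")
  g <- graph_new()
  out <- build_ghostc3(g, 0L, c1, c2, as.integer(n), activation)
  new_block_spec("GhostC3", g, out, list(c1 = c1, c2 = c2, n = as.integer(n),
                                         activation = activation))
}
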