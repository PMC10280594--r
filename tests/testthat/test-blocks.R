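test_that("GhostConv parameter counts match the hand counts", {
  # 16*16*1 + 32 + 16*25 + 32
  expect_equal(block_params(ghostconv_spec(16, 32, 1, 1)), 720)
  # 3x3 primary: fewer than a standard 3x3 conv 16->32 with batch-norm (4672)
  expect_equal(block_params(ghostconv_spec(16, 32, 3, 1)), 2768)
  expect_equal(block_params(cbs_spec(16, 32, 3, 1)), 4672)
  expect_lt(block_params(ghostconv_spec(16, 32, 3, 1)),
            block_params(cbs_spec(16, 32, 3, 1)))
})

test_that("invalid block specs are rejected", {
  expect_error(ghostconv_spec(16, 31), "even")
  expect_error(ghostbottleneck_spec(32, 32, stride = 3), "stride")
  expect_error(ghostbottleneck_spec(32, 64, stride = 1), "c1 == c2")
  expect_error(ghostc3_spec(64, 64, n = 0), "n")
  expect_error(c3_spec(64, 64, n = 0), "n")
  expect_error(cbs_spec(0, 8), "c1")
  expect_error(cbs_spec(8, 8, k = 2), "odd")
  expect_error(spp_spec(8, 8, pool_kernels = c(2, 4)), "odd")
})

test_that("GhostC3 uses strictly fewer parameters than C3 at equal shape", {
  for (cfgs in list(c(64, 64, 1), c(128, 128, 2), c(256, 256, 1),
                    c(96, 64, 3))) {
    expect_lt(block_params(ghostc3_spec(cfgs[1], cfgs[2], cfgs[3])),
              block_params(c3_spec(cfgs[1], cfgs[2], cfgs[3])))
  }
})

test_that("GhostC3 stacks exactly n ghost bottlenecks", {
  count_adds <- function(spec)
    sum(vapply(spec$graph, function(nd) nd$op == "add", logical(1)))
  expect_equal(count_adds(ghostc3_spec(64, 64, 2)), 2)
  expect_equal(count_adds(ghostc3_spec(64, 64, 5)), 5)
})

test_that("block parameter counts equal the independent per-layer oracle", {
  set.seed(42)
  for (rep in 1:50) {
    kind <- sample(c("cbs", "focus", "spp", "c3", "ghostconv",
                     "ghostbottleneck", "ghostc3"), 1)
    c1 <- 2 * sample(2:32, 1)
    c2 <- 2 * sample(2:32, 1)
    spec <- switch(kind,
      cbs = cbs_spec(c1, c2, sample(c(1, 3, 5), 1), sample(1:2, 1)),
      focus = focus_spec(c1, c2, 3),
      spp = spp_spec(c1, c2),
      c3 = c3_spec(c1, c2, sample(1:3, 1)),
      ghostconv = ghostconv_spec(c1, c2, sample(c(1, 3), 1)),
      ghostbottleneck = if (sample(2, 1) == 1)
        ghostbottleneck_spec(c1, c1, stride = 1)
      else ghostbottleneck_spec(c1, c2, stride = 2),
      ghostc3 = ghostc3_spec(c1, c2, sample(1:3, 1)))
    expect_equal(block_params(spec), oracle_block_params(spec),
                 info = paste(kind, c1, c2))
  }
})

test_that("ghost bottleneck strides behave as documented on real tensors", {
  fs <- asNamespace("fishseg")
  run_block <- function(builder, c1, c2, stride, H) {
    g <- fs$graph_new()
    inp <- fs$graph_add(g, "input", integer(0), c = c1)
    out <- builder(g, inp, c1, c2, stride, "Swish")
    model <- structure(list(cfg = list(num_classes = 1), nodes = g$nodes,
                            input = inp, det_nodes = integer(0),
                            seg_node = NA_integer_), class = "fishseg_model")
    model <- fs$init_weights(model, seed = 1)
    x <- array(rnorm(H * H * c1), c(H, H, c1, 1))
    list(x = x, y = fs$forward_graph(model, x)$outs[[out]], model = model,
         out = out, g = g)
  }
  r1 <- run_block(fs$build_ghostbottleneck, 16, 16, 1L, 12)
  expect_equal(dim(r1$y), dim(r1$x))          # stride 1 preserves shape
  r2 <- run_block(fs$build_ghostbottleneck, 16, 32, 2L, 12)
  expect_equal(dim(r2$y), c(6, 6, 32, 1))     # stride 2 halves space
  # stride-1 residual adds zero on zero input: output equals cheap-path-only
  x0 <- array(0, c(8, 8, 16, 1))
  y0 <- fs$forward_graph(r1$model, x0)$outs[[r1$out]]
  add_node <- r1$g$nodes[[r1$out]]
  expect_equal(add_node$op, "add")
  branch <- fs$forward_graph(r1$model, x0)$outs[[add_node$from[2]]]
  expect_equal(y0, x0 + branch)
})
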