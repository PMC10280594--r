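test_that("published parameter totals are reproduced exactly", {
  m_c3 <- build_model(model_config(seg_head_variant = "C3"), seed = 1)
  m_g <- build_model(model_config(seg_head_variant = "GhostC3"), seed = 1)
  expect_identical(count_parameters(m_c3), 7731361)
  expect_identical(count_parameters(m_g), 7577985)
  expect_identical(count_parameters(m_c3) - count_parameters(m_g), 153376)
  # plain 80-class detector rounds to 7.3 M
  m80 <- build_model(model_config(num_classes = 80, seg_head_variant = "none",
                                  activation = "Swish"), seed = 1)
  expect_equal(round(count_parameters(m80) / 1e6, 1), 7.3)
})

test_that("instantiated weights match the closed-form count and the oracle", {
  for (variant in c("C3", "GhostC3", "none")) {
    m <- build_model(model_config(seg_head_variant = variant), seed = 2)
    closed <- sum(vapply(m$nodes, asNamespace("fishseg")$prim_params,
                         numeric(1)))
    expect_identical(count_parameters(m), closed)
    expect_identical(count_parameters(m), oracle_instantiated_params(m))
  }
})

test_that("only the segmentation head differs between C3 and GhostC3 models", {
  m_c3 <- build_model(model_config(seg_head_variant = "C3"), seed = 1)
  m_g <- build_model(model_config(seg_head_variant = "GhostC3"), seed = 1)
  # node-by-node, backbone/neck/detect are identical kinds and widths
  pre <- seq_len(min(m_c3$seg_nodes0, m_g$seg_nodes0) - 1)
  kinds_c3 <- vapply(m_c3$nodes[pre], `[[`, character(1), "op")
  kinds_g <- vapply(m_g$nodes[pre], `[[`, character(1), "op")
  expect_identical(kinds_c3, kinds_g)
  p <- asNamespace("fishseg")$prim_params
  expect_identical(vapply(m_c3$nodes[pre], p, numeric(1)),
                   vapply(m_g$nodes[pre], p, numeric(1)))
})

test_that("activation swap changes no parameter count", {
  a <- count_parameters(build_model(model_config(activation = "Swish"),
                                    seed = 1))
  b <- count_parameters(build_model(model_config(activation = "HardSwish"),
                                    seed = 1))
  expect_identical(a, b)
})

test_that("forward produces the contracted shapes and is deterministic", {
  m <- build_model(model_config(img_size = 64), seed = 5)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- forward(m, x)
  expect_equal(dim(out$det_maps[[1]]), c(2, 3, 8, 8, 6))
  expect_equal(dim(out$det_maps[[2]]), c(2, 3, 4, 4, 6))
  expect_equal(dim(out$det_maps[[3]]), c(2, 3, 2, 2, 6))
  expect_equal(dim(out$seg_logits), c(2, 2, 64, 64))
  out2 <- forward(m, x)
  expect_identical(out, out2)
  expect_error(forward(m, array(0, c(32, 32, 3, 1))), "shape error")
})

test_that("zeroed weights give class-uniform segmentation softmax", {
  m <- build_model(model_config(img_size = 64), seed = 6)
  for (i in seq_along(m$nodes)) {
    w <- m$nodes[[i]]$weights
    if (is.null(w)) next
    for (nm in setdiff(names(w), c("rm", "rv")))
      m$nodes[[i]]$weights[[nm]][] <- 0
  }
  out <- forward(m, array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  # both class logits identical -> uniform softmax
  expect_equal(out$seg_logits[1, 1, , ], out$seg_logits[1, 2, , ])
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(img_size = 100), "divisible by 32")
  expect_error(model_config(seg_classes = 3), "seg_classes")
  expect_error(build_model(model_config(seg_tap_layer = 99)), "out of range")
  expect_error(build_model(model_config(seg_tap_channels = 256)),
               "nominal width")
})

test_that("shifting the input by one stride-32 cell shifts the coarse det map", {
  m <- build_model(model_config(img_size = 128, seg_head_variant = "none"),
                   seed = 7)
  set.seed(8)
  # a bright interior blob on a flat background
  x <- array(0.2, c(128, 128, 3, 1))
  x[33:64, 33:64, , 1] <- 1
  x2 <- array(0.2, c(128, 128, 3, 1))
  x2[65:96, 33:64, , 1] <- 1          # shifted 32 px down (rows)
  o1 <- forward(m, x)$det_maps[[3]]   # stride 32: 4x4 cells
  o2 <- forward(m, x2)$det_maps[[3]]
  obj1 <- o1[1, , , , 5]
  obj2 <- o2[1, , , , 5]
  i1 <- which(obj1 == max(obj1), arr.ind = TRUE)[1, ]
  i2 <- which(obj2 == max(obj2), arr.ind = TRUE)[1, ]
  expect_equal(unname(i2[2] - i1[2]), 1)   # argmax row moved one cell
  expect_equal(unname(i2[3] - i1[3]), 0)   # column unchanged
})

test_that("model configurations round-trip through YAML", {
  cfg <- model_config(num_classes = 3, img_size = 320,
                      seg_head_variant = "C3", activation = "Swish")
  f <- tempfile(fileext = ".yaml")
  model_config_to_yaml(cfg, f)
  back <- model_config_from_yaml(f)
  expect_equal(back[names(back) != "anchors"],
               cfg[names(cfg) != "anchors"])
  expect_equal(back$anchors, cfg$anchors, ignore_attr = TRUE)
  unlink(f)
})
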