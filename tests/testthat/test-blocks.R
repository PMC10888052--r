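# Attention mechanisms and the DSPC convolution block.

test_that("all four attention ops preserve shape and contract elementwise", {
  x <- rvol(4, 4, 4, 8, seed = 11)
  for (fn in list(function(v) channel_attention(v, reduction = 4),
                  function(v) spatial_attention(v, kernel = 3),
                  function(v) coordinate_attention(v, reduction = 4),
                  function(v) cbam(v, reduction = 4, kernel = 3))) {
    set.seed(5)
    y <- fn(x)
    expect_identical(dim(y), dim(x))
    expect_true(all(abs(y) <= abs(x) + 1e-12))
  }
  # energy never increases under sigmoid gating
  set.seed(6)
  y <- coordinate_attention(rvol(4, 6, 8, 8, seed = 2))
  expect_lte(sum(y^2), sum(rvol(4, 6, 8, 8, seed = 2)^2))
})

test_that("channel attention with symmetric weights gates all channels equally", {
  x <- array(rep(seq_len(8), each = 4 * 4 * 4), dim = c(4, 4, 4, 8))
  x[] <- 1.7                      # identical constant on every channel
  ly <- nlinet:::channel_attention_layer(8, reduction = 4)
  for (pn in names(ly$params)) ly$params[[pn]][] <- 0.3   # symmetric init
  g <- nlinet:::catt_gates(ly, x)$a
  expect_lt(max(g) - min(g), 1e-6)
  expect_true(all(g > 0 & g < 1))
})

test_that("spatial attention: constant input gives a spatially constant gate", {
  x <- array(0, dim = c(6, 6, 6, 4))
  for (c in 1:4) x[, , , c] <- c * 0.5
  set.seed(3)
  ly <- nlinet:::spatial_attention_layer(kernel = 3)
  y <- nlinet:::ly_forward(ly, x, training = TRUE)
  gate <- y[, , , 1] / x[, , , 1]
  # interior voxels share the gate; borders differ through zero padding
  inner <- gate[2:5, 2:5, 2:5]
  expect_lt(stats::var(as.vector(inner)), 1e-10)
  expect_error(spatial_attention(x, kernel = 4), "odd")
})

test_that("cbam equals the manual channel-then-spatial composition", {
  x <- rvol(6, 6, 6, 4, seed = 21)
  set.seed(9)
  ly <- nlinet:::cbam_layer(4, reduction = 2, kernel = 3)
  direct <- nlinet:::ly_forward(ly, x)
  manual <- nlinet:::ly_forward(ly$satt, nlinet:::ly_forward(ly$catt, x))
  expect_equal(direct, manual, tolerance = 1e-12)
  expect_identical(dim(direct), dim(x))
})

test_that("coordinate attention: axis-constant input yields axis-constant gates", {
  # input varies only along H, so the W and D gates must be constant per axis
  x <- array(rep(seq_len(6), times = 4 * 8 * 3), dim = c(6, 4, 8, 3))
  set.seed(13)
  ly <- nlinet:::coordinate_attention_layer(3, reduction = 1)
  g <- nlinet:::coord_gates(ly, x)
  expect_lt(max(apply(g$gw, 2, function(v) max(v) - min(v))), 1e-12)
  expect_lt(max(apply(g$gd, 2, function(v) max(v) - min(v))), 1e-12)
  expect_error(coordinate_attention(array(1, dim = c(0, 2, 2, 1))),
               "degenerate|length 0")
})

test_that("dspc block obeys its channel contract and rejects bad input", {
  cfg <- block_config(8, 16, spatial_kernel = 7, channel_reduction = 4)
  x <- rvol(8, 8, 8, 8, seed = 31)
  set.seed(2)
  y <- dspc_forward(x, cfg)
  expect_identical(dim(y), c(8L, 8L, 8L, 16L))
  set.seed(2)
  blk <- build_block(cfg)
  expect_error(nlinet:::ly_forward(blk, rvol(8, 8, 8, 4, seed = 1)),
               "channels")
  expect_error(block_config(8, 16, att1 = "swirl"), "arg")
})

test_that("block spatial shape is preserved for every odd kernel", {
  for (k in c(1, 3, 5)) {
    cfg <- block_config(3, 5, depthwise_kernel = k, spatial_kernel = 3,
                        channel_reduction = 2)
    set.seed(k)
    y <- dspc_forward(rvol(5, 7, 6, 3, seed = 41), cfg)
    expect_identical(dim(y)[1:3], c(5L, 7L, 6L))
  }
})

test_that("dspc parameter count equals the layer-by-layer enumeration", {
  cfg <- block_config(8, 16, depthwise_kernel = 3, att1 = "spatial",
                      att2 = "channel", spatial_kernel = 7,
                      channel_reduction = 4)
  set.seed(1)
  blk <- build_block(cfg)
  # oracle: enumerate learnable scalars one layer at a time
  expected <- sum(
    27 * 8,             # depthwise conv, bias-free
    2 * 8,              # gn1 gamma/beta
    2 * 7^3 + 1,        # spatial attention gate conv
    8 * 16,             # pointwise conv, bias-free
    2 * 16,             # gn2
    4 * 16 + 4 + 16 * 4 + 16,  # channel attention MLP (hidden = 16/4)
    8 * 16 + 16)        # residual projection conv (with bias)
  expect_identical(count_parameters(blk), as.integer(expected) * 1)
})

test_that("with both attention slots off the block reduces to plain DSC, and
           saturated gates reproduce it bit-for-bit", {
  cfg <- block_config(4, 6, spatial_kernel = 3, channel_reduction = 2)
  set.seed(7)
  blk <- build_block(cfg)
  x <- rvol(6, 6, 4, 4, seed = 51)
  # saturate both gates at 1: zero the gate weights, push the biases high
  a1 <- blk$layers$att1
  a1$conv$params$weight[] <- 0
  a1$conv$params$bias[] <- 1e3
  a2 <- blk$layers$att2
  a2$params$w1[] <- 0; a2$params$b1[] <- 0
  a2$params$w2[] <- 0; a2$params$b2[] <- 1e3
  y_sat <- nlinet:::ly_forward(blk, x)
  blk$layers$att1 <- NULL
  blk$layers$att2 <- NULL
  y_dsc <- nlinet:::ly_forward(blk, x)
  expect_identical(y_sat, y_dsc)
  # the dsc type builds without attention layers at all
  set.seed(7)
  dsc <- build_block(block_config(4, 6, type = "dsc"))
  expect_false(any(grepl("att", names(nlinet:::leaf_layers(dsc)))))
})

test_that("gradients reach every learnable block parameter and match finite
           differences", {
  cfg <- block_config(3, 4, spatial_kernel = 3, channel_reduction = 2)
  set.seed(17)
  blk <- build_block(cfg)
  x <- rvol(5, 5, 4, 3, seed = 61)
  tgt <- rvol(5, 5, 4, 4, seed = 62)
  lossfn <- function() {
    y <- nlinet:::ly_forward(blk, x, training = TRUE)
    sum((y - tgt)^2)
  }
  run_backward <- function() {
    nlinet:::zero_grads(blk)
    y <- nlinet:::ly_forward(blk, x, training = TRUE)
    nlinet:::ly_backward(blk, 2 * (y - tgt))
  }
  run_backward()
  leaves <- nlinet:::leaf_layers(blk)
  leaves <- leaves[vapply(leaves, function(l) length(l$params) > 0, TRUE)]
  for (l in leaves)
    for (g in l$grads) expect_true(any(g != 0), label = l$name)
  set.seed(5)
  for (trial in 1:12) {
    l <- leaves[[sample(length(leaves), 1)]]
    pn <- names(l$params)[sample(length(l$params), 1)]
    idx <- sample(length(l$params[[pn]]), 1)
    run_backward()
    g_an <- l$grads[[pn]][idx]
    g_num <- num_grad(lossfn, l, pn, idx)
    expect_lt(abs(g_an - g_num) / max(1e-6, abs(g_an) + abs(g_num)), 1e-4)
  }
})
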