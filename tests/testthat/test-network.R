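# Full network assembly, forward contract, prediction, checkpoints.

test_that("forward preserves resolution, bounds outputs, and is deterministic", {
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  x <- rvol(8, 8, 8, 2, seed = 1)
  p1 <- model_forward(m, x)
  expect_identical(dim(p1), c(8L, 8L, 8L, 3L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(model_forward(m, x), p1)
  # same seed -> identical weights -> identical outputs
  m2 <- build_model(cfg)
  expect_identical(model_forward(m2, x), p1)
  # input validation
  expect_error(model_forward(m, rvol(8, 8, 8, 3, seed = 2)), "channels")
  expect_error(model_forward(m, rvol(10, 8, 8, 2, seed = 3)),
               "divisible")
})

test_that("every ablation row is constructible from configuration alone", {
  x <- rvol(8, 8, 8, 2, seed = 4)
  # DSPC attention-slot grid (Att_1 x Att_2)
  for (a1 in c("none", "spatial"))
    for (a2 in c("none", "coordinate", "channel", "cbam")) {
      cfg <- tiny_cfg(block = list(att1 = a1, att2 = a2))
      p <- model_forward(build_model(cfg), x)
      expect_identical(dim(p), c(8L, 8L, 8L, 3L))
    }
  # skip-connection attention variants
  for (sk in c("none", "coordinate", "cbam", "spatial", "channel")) {
    cfg <- tiny_cfg(skip_attention = sk)
    expect_identical(dim(model_forward(build_model(cfg), x)),
                     c(8L, 8L, 8L, 3L))
  }
  # block families and MFP on/off
  for (ty in c("conv", "dsc", "dspc")) for (mfp in c(TRUE, FALSE)) {
    cfg <- tiny_cfg(block = list(type = ty), use_mfp = mfp)
    expect_identical(dim(model_forward(build_model(cfg), x)),
                     c(8L, 8L, 8L, 3L))
  }
})

test_that("skip_attention = 'none' leaves plain concatenation on the skips", {
  m <- build_model(tiny_cfg(skip_attention = "none"))
  expect_false(any(grepl("skipatt", names(nlinet:::leaf_layers(m)))))
})

test_that("removing the MFP paths removes exactly the pyramid bookkeeping rows", {
  cfg_on <- tiny_cfg()
  cfg_off <- tiny_cfg(use_mfp = FALSE)
  ra <- model_complexity(cfg_on, c(8, 8, 8))
  rb <- model_complexity(cfg_off, c(8, 8, 8))
  only_on <- setdiff(ra$breakdown$layer, rb$breakdown$layer)
  expect_true(all(grepl("^mfp|skipatt$", only_on) |
                    grepl("^enc[0-9]+\\.skipatt", only_on)))
  expect_lt(rb$total_params, ra$total_params)
  # bookkeeping consistency: analytic == enumeration on both variants
  expect_equal(count_parameters(build_model(cfg_on)), ra$total_params)
  expect_equal(count_parameters(build_model(cfg_off)), rb$total_params)
})

test_that("prediction thresholds with ties mapping to one", {
  m <- build_model(tiny_cfg())
  x <- rvol(8, 8, 8, 2, seed = 5)
  pr <- model_predict(m, x, threshold = 0.5)
  expect_identical(pr$masks, (pr$probabilities >= 0.5) * 1)
  expect_identical(dim(pr$masks), dim(pr$probabilities))
  # an all-zero head makes p = 0.5 everywhere: the tie rule forces all ones
  m$head$params$weight[] <- 0
  m$head$params$bias[] <- 0
  pr <- model_predict(m, x, threshold = 0.5)
  expect_true(all(pr$masks == 1))
  expect_error(model_predict(m, x, threshold = 1), "threshold")
  expect_error(model_predict(m, x, threshold = 0), "threshold")
})

test_that("enforce_nesting makes the three masks nested", {
  m <- build_model(tiny_cfg(seed = 9))
  x <- rvol(8, 8, 8, 2, seed = 6)
  pr <- model_predict(m, x, threshold = 0.5, enforce_nesting = TRUE)
  et <- pr$masks[, , , 1]; tc <- pr$masks[, , , 2]; wt <- pr$masks[, , , 3]
  expect_true(all(et <= tc) && all(tc <= wt))
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(tiny_cfg(seed = 3))
  x <- rvol(8, 8, 8, 2, seed = 7)
  p <- model_forward(m, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(model_forward(m2, x), p)
  unlink(ck)
})

test_that("model gradients match finite differences and reach every parameter", {
  cfg <- tiny_cfg(seed = 7)
  m <- build_model(cfg)
  x <- rvol(8, 8, 4, 2, seed = 8)
  lab <- withr::with_seed(9, array(sample(0:3, 8 * 8 * 4, replace = TRUE),
                                   dim = c(8, 8, 4)))
  lossfn <- function() {
    p <- model_forward(m, x, training = TRUE)
    combo_loss(p, lab)$total
  }
  run_backward <- function() {
    nlinet:::zero_grads(m)
    p <- model_forward(m, x, training = TRUE)
    lv <- combo_loss(p, lab, grad = TRUE)
    nlinet:::model_backward(m, lv$grad)
  }
  run_backward()
  leaves <- nlinet:::leaf_layers(m)
  leaves <- leaves[vapply(leaves, function(l) length(l$params) > 0, TRUE)]
  for (l in leaves)
    for (g in l$grads) expect_true(any(g != 0), label = l$name)
  set.seed(10)
  for (trial in 1:15) {
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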