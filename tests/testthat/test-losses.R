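# Sub-region masks, weights, Dice / weighted-cross-entropy / combo losses.

lab4 <- function(codes) array(codes, dim = c(length(codes), 1, 1))

test_that("sub-region masks follow the nesting definition", {
  sm <- subregion_masks(lab4(c(0, 1, 2, 3)))       # bg, NCR, ED, ET
  expect_equal(as.vector(sm$masks[, 1, 1, "ET"]), c(0, 0, 0, 1))
  expect_equal(as.vector(sm$masks[, 1, 1, "TC"]), c(0, 1, 0, 1))
  expect_equal(as.vector(sm$masks[, 1, 1, "WT"]), c(0, 1, 1, 1))
  sm0 <- subregion_masks(array(0L, dim = c(3, 3, 3)))
  expect_true(all(sm0$masks == 0))
  expect_error(subregion_masks(lab4(c(0, 5))), "unknown label")
})

test_that("mask counts agree with a per-voxel loop oracle and always nest", {
  for (seed in 1:5) {
    lab <- withr::with_seed(seed, array(sample(0:3, 6 * 5 * 4, replace = TRUE,
                                               prob = c(0.7, 0.1, 0.15, 0.05)),
                                        dim = c(6, 5, 4)))
    sm <- subregion_masks(lab)
    # oracle: tally classes voxel by voxel, combine by the union rules
    n_et <- 0; n_tc <- 0; n_wt <- 0
    for (v in as.vector(lab)) {
      if (v == 3) n_et <- n_et + 1
      if (v == 3 || v == 1) n_tc <- n_tc + 1
      if (v != 0) n_wt <- n_wt + 1
    }
    expect_equal(unname(sm$counts), c(n_et, n_tc, n_wt))
    expect_true(all(sm$masks[, , , 1] <= sm$masks[, , , 2]))
    expect_true(all(sm$masks[, , , 2] <= sm$masks[, , , 3]))
  }
})

test_that("region weights implement |WT|/|k| with the empty-region convention", {
  # counts (50, 200, 1000): 50 ET, 150 NCR, 800 ED voxels
  lab <- array(c(rep(3, 50), rep(1, 150), rep(2, 800)), dim = c(1000, 1, 1))
  w <- region_weights(subregion_masks(lab))
  expect_equal(unname(w[1:3]), c(20, 5, 1))
  # empty ET
  lab <- array(c(rep(1, 10)), dim = c(10, 1, 1))
  w <- region_weights(subregion_masks(lab))
  expect_equal(unname(w[1:3]), c(0, 1, 1))
  # equal counts
  lab <- array(rep(3, 7), dim = c(7, 1, 1))
  expect_equal(unname(region_weights(subregion_masks(lab))[1:3]), c(1, 1, 1))
})

test_that("dice loss identities and the worked single-region example hold", {
  sm <- subregion_masks(lab4(c(0, 1, 2, 3, 0, 3)))
  expect_lt(dice_loss(sm$masks, sm), 1e-4)               # perfect prediction
  p0 <- array(0, dim = dim(sm$masks))
  expect_gt(dice_loss(p0, sm), 1 - 1e-3)                 # total miss
  # single region: y = (1,1,0,0), p = (1, .5, .5, 0) -> loss 0.25 at eps = 0
  y <- array(c(1, 1, 0, 0), dim = c(4, 1, 1, 1))
  p <- array(c(1, 0.5, 0.5, 0), dim = c(4, 1, 1, 1))
  expect_equal(dice_loss(p, y, eps = 0), 0.25, tolerance = 1e-12)
})

test_that("weighted cross-entropy matches the worked example and is linear in w", {
  y <- array(c(1, 0), dim = c(2, 1, 1, 1))
  p <- array(c(exp(-1), 0.42), dim = c(2, 1, 1, 1))
  expect_equal(wce_loss(p, y, w = 1), 0.5, tolerance = 1e-9)
  expect_equal(wce_loss(p, y, w = 2), 1.0, tolerance = 1e-9)
  # p = 1 on every positive voxel -> loss 0 up to the clamp
  expect_lt(wce_loss(array(1, dim = dim(y)), y, w = 3), 1e-5)
})

test_that("combo loss is additive and matches a per-voxel loop oracle", {
  lab <- withr::with_seed(3, array(sample(0:3, 4 * 3 * 2, replace = TRUE),
                                   dim = c(4, 3, 2)))
  sm <- subregion_masks(lab)
  p <- withr::with_seed(4, array(runif(4 * 3 * 2 * 3, 0.05, 0.95),
                                 dim = c(4, 3, 2, 3)))
  lv <- combo_loss(p, lab)
  expect_equal(lv$total, lv$dice_part + lv$wce_part, tolerance = 1e-12)
  w <- region_weights(sm)
  expect_equal(lv$dice_part, dice_loss(p, sm$masks), tolerance = 1e-12)
  expect_equal(lv$wce_part, wce_loss(p, sm$masks, w), tolerance = 1e-12)
  # loop oracle
  N <- 4 * 3 * 2
  dice_terms <- numeric(3)
  wce_acc <- 0
  for (k in 1:3) {
    syp <- 0; sy <- 0; sp <- 0
    for (i3 in 1:2) for (i2 in 1:3) for (i1 in 1:4) {
      yv <- sm$masks[i1, i2, i3, k]
      pv <- p[i1, i2, i3, k]
      syp <- syp + yv * pv; sy <- sy + yv; sp <- sp + pv
      wce_acc <- wce_acc - w[k] * yv * log(pv)
    }
    dice_terms[k] <- (syp + 1e-5) / (sy + sp + 1e-5)
  }
  oracle <- (1 - (2 / 3) * sum(dice_terms)) + wce_acc / N
  expect_equal(lv$total, as.numeric(oracle), tolerance = 1e-6)
})

test_that("losses are invariant to voxel permutations", {
  sm <- subregion_masks(withr::with_seed(5, array(sample(0:3, 24, TRUE),
                                                  dim = c(4, 3, 2))))
  p <- withr::with_seed(6, array(runif(24 * 3), dim = c(4, 3, 2, 3)))
  perm <- withr::with_seed(7, sample(24))
  pm <- array(apply(matrix(p, 24), 2, function(col) col[perm]),
              dim = dim(p))
  ym <- array(apply(matrix(sm$masks, 24), 2, function(col) col[perm]),
              dim = dim(sm$masks))
  w <- region_weights(sm)
  expect_equal(dice_loss(p, sm$masks), dice_loss(pm, ym), tolerance = 1e-12)
  expect_equal(wce_loss(p, sm$masks, w), wce_loss(pm, ym, w),
               tolerance = 1e-12)
})

test_that("combo loss decreases monotonically along p = t*y toward the target", {
  lab <- array(c(rep(0, 30), rep(2, 15), rep(1, 10), rep(3, 5)),
               dim = c(60, 1, 1))
  y <- subregion_masks(lab)
  ts <- seq(0.1, 1, by = 0.1)
  vals <- vapply(ts, function(t) combo_loss(t * y$masks, y)$total, 1)
  expect_true(all(diff(vals) < 0))
})

test_that("the positive-only WCE is degenerate at p = 1 but the combo is not", {
  lab <- array(c(rep(0, 50), rep(2, 6), rep(1, 3), rep(3, 1)),
               dim = c(60, 1, 1))
  y <- subregion_masks(lab)
  w <- region_weights(y)
  ones <- array(1, dim = dim(y$masks))
  # WCE alone is minimized by predicting 1 everywhere
  expect_lt(wce_loss(ones, y$masks, w), 1e-5)
  p_rand <- withr::with_seed(8, array(runif(length(ones), 0.2, 0.9),
                                      dim = dim(ones)))
  expect_gt(wce_loss(p_rand, y$masks, w), wce_loss(ones, y$masks, w))
  # ...but the combo (Dice term) penalizes the all-ones degenerate solution
  expect_gt(combo_loss(ones, y)$total, combo_loss(y$masks, y)$total + 0.1)
})

test_that("loss gradients match finite differences", {
  lab <- withr::with_seed(11, array(sample(0:3, 24, TRUE), dim = c(4, 3, 2)))
  p <- withr::with_seed(12, array(runif(24 * 3, 0.1, 0.9),
                                  dim = c(4, 3, 2, 3)))
  lv <- combo_loss(p, lab, grad = TRUE)
  eps <- 1e-6
  set.seed(13)
  for (trial in 1:10) {
    i <- sample(length(p), 1)
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    g_num <- (combo_loss(pp, lab)$total - combo_loss(pm, lab)$total) / (2 * eps)
    expect_lt(abs(lv$grad[i] - g_num) / max(1e-6, abs(g_num) + abs(lv$grad[i])),
              1e-4)
  }
})
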