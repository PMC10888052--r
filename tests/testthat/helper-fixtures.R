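# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

rvol <- function(h, w, d, c, seed = 1) {
  withr::with_seed(seed, array(rnorm(h * w * d * c), dim = c(h, w, d, c)))
}

tiny_cfg <- function(..., levels = 2, stem_channels = 4,
                     encoder_channels = c(6, 8), input_channels = 2,
                     block = list(), seed = 1) {
  block <- modifyList(list(channel_reduction = 2, spatial_kernel = 3), block)
  model_config(levels = levels, stem_channels = stem_channels,
               encoder_channels = encoder_channels,
               input_channels = input_channels, block = block, seed = seed,
               ...)
}

# ---- brute-force surface-distance oracle (per-voxel loops, all pairs) ------

surface_voxels_bf <- function(m) {
  d <- dim(m)
  offs <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
               c(0, 0, -1), c(0, 0, 1))
  out <- list()
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!m[i, j, k]) next
    surf <- FALSE
    for (off in offs) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !m[ii, jj, kk]) { surf <- TRUE; break }
    }
    if (surf) out[[length(out) + 1L]] <- c(i, j, k)
  }
  do.call(rbind, out)
}

hd_bf <- function(P, Y, spacing = c(1, 1, 1), percentile = 95) {
  sp <- surface_voxels_bf(array(as.logical(P), dim = dim(P)))
  sy <- surface_voxels_bf(array(as.logical(Y), dim = dim(Y)))
  spx <- sweep(sp, 2, spacing, "*")
  syx <- sweep(sy, 2, spacing, "*")
  d2 <- outer(rowSums(spx^2), rowSums(syx^2), "+") - 2 * spx %*% t(syx)
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  dpy <- apply(dmat, 1, min)
  dyp <- apply(dmat, 2, min)
  q <- percentile / 100
  max(quantile(dpy, q, names = FALSE), quantile(dyp, q, names = FALSE))
}

random_blob <- function(dims, seed) {
  withr::with_seed(seed, {
    m <- array(FALSE, dim = dims)
    ctr <- sapply(dims, function(n) runif(1, 2, n - 1))
    rad <- sapply(dims, function(n) runif(1, 1.2, n / 2.5))
    gh <- (seq_len(dims[1]) - ctr[1]) / rad[1]
    gw <- (seq_len(dims[2]) - ctr[2]) / rad[2]
    gd <- (seq_len(dims[3]) - ctr[3]) / rad[3]
    m <- outer(outer(gh^2, gw^2, "+"), gd^2, "+") <= 1
    if (!any(m)) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                   ceiling(dims[3] / 2)] <- TRUE
    m
  })
}

# finite-difference gradient of a scalar-valued function of one layer param
num_grad <- function(lossfn, layer, pn, idx, eps = 1e-5) {
  orig <- layer$params[[pn]][idx]
  layer$params[[pn]][idx] <- orig + eps
  lp <- lossfn()
  layer$params[[pn]][idx] <- orig - eps
  lm <- lossfn()
  layer$params[[pn]][idx] <- orig
  (lp - lm) / (2 * eps)
}
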