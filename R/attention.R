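# Attention mechanisms (3-d variants). All four end in a sigmoid gate that
# multiplies the input, so every one is an elementwise contraction:
# |out| <= |in| voxel by voxel.

## ---- channel attention -----------------------------------------------------

# Squeeze-and-excitation style: global average pooling over the spatial dims,
# a two-layer bottleneck MLP (ELU inside, matching the rest of the network),
# then per-channel sigmoid gates.
channel_attention_layer <- function(channels, reduction = 4, name = "catt") {
  if (reduction < 1) stop("reduction must be >= 1")
  r <- min(reduction, channels)              # clamp: reduction <= C
  hid <- max(1L, as.integer(floor(channels / r)))
  params <- list(
    w1 = matrix(rnorm(hid * channels, sd = sqrt(2 / channels)), hid, channels),
    b1 = numeric(hid),
    w2 = matrix(rnorm(channels * hid, sd = sqrt(2 / hid)), channels, hid),
    b2 = numeric(channels))
  new_layer("nl_catt", params = params, grads = zero_like(params),
            channels = channels, hidden = hid, name = name)
}

# gate vector in (0,1), one entry per channel
catt_gates <- function(layer, x) {
  nspat <- n_voxels(x)
  s <- colMeans(matrix(x, nrow = nspat))
  z1 <- as.vector(layer$params$w1 %*% s + layer$params$b1)
  h <- elu_fn(z1)
  a <- sigmoid(as.vector(layer$params$w2 %*% h + layer$params$b2))
  list(s = s, z1 = z1, h = h, a = a)
}

ly_forward.nl_catt <- function(layer, x, training = FALSE) {
  if (n_channels(x) != layer$channels)
    stop("channel attention '", layer$name, "': channel mismatch")
  g <- catt_gates(layer, x)
  if (training) {
    layer$x <- x
    layer$cache <- g
  }
  x * bcast_channel(g$a, dim(x))
}

ly_backward.nl_catt <- function(layer, gy) {
  x <- layer$x
  cc <- layer$cache
  dims <- dim(x)
  nspat <- prod(dims[1:3])
  gx <- gy * bcast_channel(cc$a, dims)
  da <- colSums(matrix(gy * x, nrow = nspat))
  dz2 <- da * cc$a * (1 - cc$a)
  layer$grads$w2 <- layer$grads$w2 + dz2 %o% cc$h
  layer$grads$b2 <- layer$grads$b2 + dz2
  dh <- as.vector(t(layer$params$w2) %*% dz2)
  dz1 <- dh * ifelse(cc$z1 > 0, 1, exp(cc$z1))
  layer$grads$w1 <- layer$grads$w1 + dz1 %o% cc$s
  layer$grads$b1 <- layer$grads$b1 + dz1
  ds <- as.vector(t(layer$params$w1) %*% dz1)
  gx + bcast_channel(ds / nspat, dims)
}

## ---- spatial attention -----------------------------------------------------

# CBAM-style: channel-wise mean and max maps, stacked and convolved with a
# single k x k x k filter, then a per-voxel sigmoid gate shared by channels.
spatial_attention_layer <- function(kernel = 7, name = "satt") {
  if (kernel %% 2 != 1) stop("spatial attention kernel must be odd, got ", kernel)
  cv <- conv3d_layer(2, 1, kernel = kernel, bias = TRUE,
                     name = paste0(name, ".conv"))
  new_layer("nl_satt", params = list(), grads = list(), conv = cv,
            kernel = kernel, name = name)
}

leaf_layers.nl_satt <- function(obj) leaf_layers(list(obj$conv))

satt_pool <- function(x) {
  dims <- dim(x)
  C <- dims[4L]
  m <- matrix(x, ncol = C)
  mn <- rowMeans(m)
  mx <- m[, 1L]
  arg <- rep(1L, nrow(m))
  if (C > 1) for (c in 2:C) {
    upd <- m[, c] > mx
    mx[upd] <- m[upd, c]
    arg[upd] <- c
  }
  list(pool = array(c(mn, mx), dim = c(dims[1:3], 2L)), arg = arg)
}

ly_forward.nl_satt <- function(layer, x, training = FALSE) {
  p <- satt_pool(x)
  z <- ly_forward(layer$conv, p$pool, training)
  g <- sigmoid(z)
  if (training) {
    layer$x <- x
    layer$g <- g
    layer$arg <- p$arg
  }
  x * as.vector(g)                 # gate broadcasts over channels (recycling)
}

ly_backward.nl_satt <- function(layer, gy) {
  x <- layer$x
  dims <- dim(x)
  C <- dims[4L]
  nspat <- prod(dims[1:3])
  g <- as.vector(layer$g)
  gx <- gy * g
  dg <- rowSums(matrix(gy * x, nrow = nspat))
  dz <- array(dg * g * (1 - g), dim = c(dims[1:3], 1L))
  gpool <- ly_backward(layer$conv, dz)
  gmn <- as.vector(gpool[, , , 1L])
  gmx <- as.vector(gpool[, , , 2L])
  gxm <- matrix(gx, nrow = nspat)
  gxm <- gxm + gmn / C             # mean path reaches every channel equally
  idx <- cbind(seq_len(nspat), layer$arg)
  gxm[idx] <- gxm[idx] + gmx       # max path reaches the argmax channel
  array(gxm, dim = dims)
}

## ---- coordinate attention --------------------------------------------------

# One pooled descriptor per spatial axis (3 axes in 3-d), passed through a
# shared bottleneck, then per-axis sigmoid gates whose outer product scales x.
coordinate_attention_layer <- function(channels, reduction = 4, name = "coord") {
  r <- min(max(1, reduction), channels)
  hid <- max(1L, as.integer(floor(channels / r)))
  params <- list(
    w1 = matrix(rnorm(hid * channels, sd = sqrt(2 / channels)), hid, channels),
    b1 = numeric(hid),
    wh = matrix(rnorm(channels * hid, sd = sqrt(2 / hid)), channels, hid),
    bh = numeric(channels),
    ww = matrix(rnorm(channels * hid, sd = sqrt(2 / hid)), channels, hid),
    bw = numeric(channels),
    wd = matrix(rnorm(channels * hid, sd = sqrt(2 / hid)), channels, hid),
    bd = numeric(channels))
  new_layer("nl_coord", params = params, grads = zero_like(params),
            channels = channels, hidden = hid, name = name)
}

coord_gates <- function(layer, x) {
  dims <- dim(x)
  H <- dims[1L]; W <- dims[2L]; D <- dims[3L]; C <- dims[4L]
  xm <- matrix(x, nrow = H * W * D)            # voxels x C
  # per-axis average pools, each (axis length) x C
  ph <- matrix(0, H, C); pw <- matrix(0, W, C); pd <- matrix(0, D, C)
  hidx <- rep_len(seq_len(H), H * W * D)
  widx <- rep(rep(seq_len(W), each = H), times = D)
  didx <- rep(seq_len(D), each = H * W)
  for (c in seq_len(C)) {
    v <- xm[, c]
    ph[, c] <- rowsum(v, hidx)[, 1] / (W * D)
    pw[, c] <- rowsum(v, widx)[, 1] / (H * D)
    pd[, c] <- rowsum(v, didx)[, 1] / (H * W)
  }
  tt <- rbind(ph, pw, pd)                      # (H+W+D) x C
  z1 <- sweep(tt %*% t(layer$params$w1), 2, layer$params$b1, "+")
  hh <- elu_fn(z1)
  sh <- hh[seq_len(H), , drop = FALSE]
  sw <- hh[H + seq_len(W), , drop = FALSE]
  sd_ <- hh[H + W + seq_len(D), , drop = FALSE]
  zh <- sweep(sh %*% t(layer$params$wh), 2, layer$params$bh, "+")
  zw <- sweep(sw %*% t(layer$params$ww), 2, layer$params$bw, "+")
  zd <- sweep(sd_ %*% t(layer$params$wd), 2, layer$params$bd, "+")
  list(gh = sigmoid(zh), gw = sigmoid(zw), gd = sigmoid(zd),
       z1 = z1, hh = hh, tt = tt, idx = list(h = hidx, w = widx, d = didx))
}

coord_gate_volume <- function(g, dims) {
  H <- dims[1L]; W <- dims[2L]; D <- dims[3L]; C <- dims[4L]
  G <- array(0, dim = dims)
  for (c in seq_len(C))
    G[, , , c] <- outer(g$gh[, c], outer(g$gw[, c], g$gd[, c]))
  G
}

ly_forward.nl_coord <- function(layer, x, training = FALSE) {
  if (n_channels(x) != layer$channels)
    stop("coordinate attention '", layer$name, "': channel mismatch")
  g <- coord_gates(layer, x)
  G <- coord_gate_volume(g, dim(x))
  if (training) {
    layer$x <- x
    layer$cache <- g
    layer$G <- G
  }
  x * G
}

ly_backward.nl_coord <- function(layer, gy) {
  x <- layer$x
  cc <- layer$cache
  dims <- dim(x)
  H <- dims[1L]; W <- dims[2L]; D <- dims[3L]; C <- dims[4L]
  gx <- gy * layer$G
  dG <- gy * x
  dgh <- matrix(0, H, C); dgw <- matrix(0, W, C); dgd <- matrix(0, D, C)
  for (c in seq_len(C)) {
    M <- dG[, , , c, drop = FALSE]
    dim(M) <- c(H, W, D)
    vw <- cc$gw[, c]; vd <- cc$gd[, c]; vh <- cc$gh[, c]
    M1 <- matrix(M, H, W * D)
    dgh[, c] <- M1 %*% as.vector(outer(vw, vd))
    MW <- matrix(aperm(M, c(2, 1, 3)), W, H * D)
    dgw[, c] <- MW %*% as.vector(outer(vh, vd))
    MD <- matrix(aperm(M, c(3, 1, 2)), D, H * W)
    dgd[, c] <- MD %*% as.vector(outer(vh, vw))
  }
  dzh <- dgh * cc$gh * (1 - cc$gh)
  dzw <- dgw * cc$gw * (1 - cc$gw)
  dzd <- dgd * cc$gd * (1 - cc$gd)
  sh <- cc$hh[seq_len(H), , drop = FALSE]
  sw <- cc$hh[H + seq_len(W), , drop = FALSE]
  sd_ <- cc$hh[H + W + seq_len(D), , drop = FALSE]
  layer$grads$wh <- layer$grads$wh + t(dzh) %*% sh
  layer$grads$bh <- layer$grads$bh + colSums(dzh)
  layer$grads$ww <- layer$grads$ww + t(dzw) %*% sw
  layer$grads$bw <- layer$grads$bw + colSums(dzw)
  layer$grads$wd <- layer$grads$wd + t(dzd) %*% sd_
  layer$grads$bd <- layer$grads$bd + colSums(dzd)
  dhh <- rbind(dzh %*% layer$params$wh,
               dzw %*% layer$params$ww,
               dzd %*% layer$params$wd)
  dz1 <- dhh * ifelse(cc$z1 > 0, 1, exp(cc$z1))
  layer$grads$w1 <- layer$grads$w1 + t(dz1) %*% cc$tt
  layer$grads$b1 <- layer$grads$b1 + colSums(dz1)
  dtt <- dz1 %*% layer$params$w1              # (H+W+D) x C
  dph <- dtt[seq_len(H), , drop = FALSE] / (W * D)
  dpw <- dtt[H + seq_len(W), , drop = FALSE] / (H * D)
  dpd <- dtt[H + W + seq_len(D), , drop = FALSE] / (H * W)
  gxm <- matrix(gx, nrow = H * W * D)
  for (c in seq_len(C))
    gxm[, c] <- gxm[, c] + dph[cc$idx$h, c] + dpw[cc$idx$w, c] +
      dpd[cc$idx$d, c]
  array(gxm, dim = dims)
}

## ---- CBAM ------------------------------------------------------------------

cbam_layer <- function(channels, reduction = 4, kernel = 7, name = "cbam") {
  new_layer("nl_cbam", params = list(), grads = list(),
            catt = channel_attention_layer(channels, reduction,
                                           paste0(name, ".ca")),
            satt = spatial_attention_layer(kernel, paste0(name, ".sa")),
            channels = channels, name = name)
}

leaf_layers.nl_cbam <- function(obj) leaf_layers(list(obj$catt, obj$satt))

ly_forward.nl_cbam <- function(layer, x, training = FALSE) {
  ly_forward(layer$satt, ly_forward(layer$catt, x, training), training)
}

ly_backward.nl_cbam <- function(layer, gy) {
  ly_backward(layer$catt, ly_backward(layer$satt, gy))
}

## ---- constructor dispatch + functional API ---------------------------------

attention_layer <- function(type, channels, reduction = 4, kernel = 7,
                            name = type) {
  switch(type,
         none = NULL,
         channel = channel_attention_layer(channels, reduction, name),
         spatial = spatial_attention_layer(kernel, name),
         coordinate = coordinate_attention_layer(channels, reduction, name),
         cbam = cbam_layer(channels, reduction, kernel, name),
         stop("unknown attention type '", type, "'"))
}

apply_attention <- function(x, layer) {
  check_volume(x, "feature map")
  if (is.null(layer)) x else ly_forward(layer, x, training = FALSE)
}

#' Channel attention
#'
#' Scales each channel of a feature map by a gate in (0, 1) computed from
#' global average pooling followed by a two-layer bottleneck MLP and a
#' sigmoid. With `layer = NULL` a fresh randomly initialized layer is drawn
#' from the current RNG stream (useful for untrained-behaviour checks);
#' trained models hold their own layers.
#'
#' @param x feature map, array `[H, W, D, C]` with finite values.
#' @param reduction bottleneck ratio of the MLP (clamped to `C`).
#' @param layer optional pre-built layer from `channel_attention_layer()`.
#' @return array of the same shape as `x`.
#' @export
channel_attention <- function(x, reduction = 4, layer = NULL) {
  check_volume(x, "feature map")
  if (is.null(layer)) layer <- channel_attention_layer(n_channels(x), reduction)
  ly_forward(layer, x, training = FALSE)
}

#' Spatial attention
#'
#' Scales every voxel by a single-channel sigmoid gate computed from the
#' channel-wise mean and max maps convolved with a `kernel^3` filter.
#'
#' @inheritParams channel_attention
#' @param kernel odd convolution kernel size of the gate filter.
#' @export
spatial_attention <- function(x, kernel = 7, layer = NULL) {
  check_volume(x, "feature map")
  if (is.null(layer)) layer <- spatial_attention_layer(kernel)
  ly_forward(layer, x, training = FALSE)
}

#' Coordinate attention
#'
#' Builds one pooled descriptor per spatial axis, passes them through a shared
#' bottleneck, and multiplies the input by the outer product of three per-axis
#' sigmoid gates.
#'
#' @inheritParams channel_attention
#' @export
coordinate_attention <- function(x, reduction = 4, layer = NULL) {
  check_volume(x, "feature map")
  if (is.null(layer)) layer <- coordinate_attention_layer(n_channels(x), reduction)
  ly_forward(layer, x, training = FALSE)
}

#' Convolutional block attention (CBAM)
#'
#' Channel attention followed by spatial attention, in that order.
#'
#' @inheritParams channel_attention
#' @param kernel odd kernel of the spatial-attention gate filter.
#' @export
cbam <- function(x, reduction = 4, kernel = 7, layer = NULL) {
  check_volume(x, "feature map")
  if (is.null(layer)) layer <- cbam_layer(n_channels(x), reduction, kernel)
  ly_forward(layer, x, training = FALSE)
}
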