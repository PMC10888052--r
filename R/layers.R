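# Leaf layers of the network. Each layer is a mutable environment holding
# `params` (named list of arrays), `grads` (same shapes), and whatever
# forward-pass caches its backward pass needs. Forward and backward are S3
# methods; backward accumulates parameter gradients and returns the gradient
# with respect to the layer input. Reverse-mode differentiation is written by
# hand per layer; a finite-difference check in the test suite guards it.

new_layer <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(cls, "nl_layer")
  e
}

ly_forward <- function(layer, x, training = FALSE) UseMethod("ly_forward")
ly_backward <- function(layer, gy) UseMethod("ly_backward")

# Flat list of leaf layers under `obj` (layer, block or model), named.
leaf_layers <- function(obj) UseMethod("leaf_layers")
leaf_layers.nl_layer <- function(obj) {
  nm <- if (is.null(obj$name)) class(obj)[1] else obj$name
  stats::setNames(list(obj), nm)
}
leaf_layers.list <- function(obj) {
  out <- list()
  for (el in obj) if (!is.null(el)) out <- c(out, leaf_layers(el))
  out
}

zero_grads <- function(obj) {
  for (ly in leaf_layers(obj)) ly$grads <- zero_like(ly$params)
  invisible(obj)
}

## ---- convolution ----------------------------------------------------------

# Stride-1 zero-padded 3-d convolution (cross-correlation), grouped.
# `groups = in_ch` gives a depthwise convolution, `kernel = 1` a pointwise one.
conv3d_layer <- function(in_ch, out_ch, kernel = 3, groups = 1, bias = TRUE,
                         name = "conv") {
  if (kernel %% 2 != 1) stop("conv kernel must be odd, got ", kernel)
  if (in_ch %% groups != 0 || out_ch %% groups != 0)
    stop("groups must divide both channel counts")
  fan_in <- kernel^3 * in_ch / groups
  w <- array(rnorm(kernel^3 * (in_ch / groups) * out_ch, sd = sqrt(2 / fan_in)),
             dim = c(kernel, kernel, kernel, in_ch / groups, out_ch))
  params <- list(weight = w)
  if (bias) params$bias <- numeric(out_ch)
  new_layer("nl_conv3d", params = params, grads = zero_like(params),
            in_ch = in_ch, out_ch = out_ch, kernel = kernel, groups = groups,
            has_bias = bias, name = name)
}

ly_forward.nl_conv3d <- function(layer, x, training = FALSE) {
  if (n_channels(x) != layer$in_ch)
    stop("conv '", layer$name, "': expected ", layer$in_ch,
         " input channels, got ", n_channels(x))
  if (training) layer$x <- x
  conv3d_fw(x, layer$params$weight,
            if (layer$has_bias) layer$params$bias else NULL, layer$groups)
}

ly_backward.nl_conv3d <- function(layer, gy) {
  bw <- conv3d_bw(layer$x, layer$params$weight, gy, layer$groups,
                  layer$has_bias)
  layer$grads$weight <- layer$grads$weight + bw$gw
  if (layer$has_bias) layer$grads$bias <- layer$grads$bias + bw$gb
  bw$gx
}

## ---- group normalization ---------------------------------------------------

# GroupNorm over `groups` channel groups; batch-size independent, which suits
# the batch-size-1 training regime. The requested group count is clamped to
# the largest divisor of C not exceeding it.
groupnorm_layer <- function(channels, groups = 8, eps = 1e-5, name = "gn") {
  g <- largest_divisor_leq(channels, groups)
  params <- list(gamma = rep(1, channels), beta = numeric(channels))
  new_layer("nl_groupnorm", params = params, grads = zero_like(params),
            channels = channels, groups = g, eps = eps, name = name)
}

ly_forward.nl_groupnorm <- function(layer, x, training = FALSE) {
  dims <- dim(x)
  C <- dims[4L]
  G <- layer$groups
  m <- matrix(x, ncol = G)          # each column = one channel group
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
  gamma_full <- rep(layer$params$gamma, each = prod(dims[1:3]))
  beta_full <- rep(layer$params$beta, each = prod(dims[1:3]))
  y <- array(as.vector(xhat) * gamma_full + beta_full, dim = dims)
  if (training) {
    layer$xhat <- xhat
    layer$invstd <- invstd
    layer$dims <- dims
  }
  y
}

ly_backward.nl_groupnorm <- function(layer, gy) {
  dims <- layer$dims
  nspat <- prod(dims[1:3])
  C <- dims[4L]
  G <- layer$groups
  xhat <- layer$xhat
  gyv <- as.vector(gy)
  xhat_v <- as.vector(xhat)
  # per-channel parameter grads
  gym <- matrix(gyv, nrow = nspat)
  prodm <- matrix(gyv * xhat_v, nrow = nspat)
  layer$grads$gamma <- layer$grads$gamma + colSums(prodm)
  layer$grads$beta <- layer$grads$beta + colSums(gym)
  # input grad per group
  gxhat <- matrix(gyv * rep(layer$params$gamma, each = nspat), ncol = G)
  n <- nrow(gxhat)
  s1 <- colMeans(gxhat)
  s2 <- colMeans(gxhat * xhat)
  gx <- sweep(gxhat, 2, s1, "-") - sweep(xhat, 2, s2, "*")
  gx <- sweep(gx, 2, layer$invstd, "*")
  array(as.vector(gx), dim = dims)
}

## ---- ELU -------------------------------------------------------------------

elu_layer <- function(alpha = 1, name = "elu") {
  new_layer("nl_elu", params = list(), grads = list(), alpha = alpha,
            name = name)
}

ly_forward.nl_elu <- function(layer, x, training = FALSE) {
  y <- elu_fn(x, layer$alpha)
  if (training) {
    layer$pos <- x > 0
    layer$y <- y
  }
  y
}

ly_backward.nl_elu <- function(layer, gy) {
  gy * ifelse(layer$pos, 1, layer$y + layer$alpha)
}

## ---- trilinear resize ------------------------------------------------------

# Trilinear interpolation with half-pixel-center (align_corners = FALSE)
# semantics; exact for integer power-of-two scale factors.
resize_layer <- function(scale, name = "resize") {
  new_layer("nl_resize", params = list(), grads = list(), scale = scale,
            name = name)
}

ly_forward.nl_resize <- function(layer, x, training = FALSE) {
  dims <- dim(x)
  out <- dims[1:3] * layer$scale
  if (any(out != round(out)) || any(out < 1))
    stop("resize: scale ", layer$scale, " does not produce integer dims from (",
         paste(dims[1:3], collapse = "x"), ")")
  if (training) layer$in_dims <- dims
  resize3d_fw(x, as.integer(out[1]), as.integer(out[2]), as.integer(out[3]))
}

ly_backward.nl_resize <- function(layer, gy) {
  d <- layer$in_dims
  resize3d_bw(gy, d[1L], d[2L], d[3L])
}
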