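# Convolution blocks. The canonical block ("dspc") follows the fixed order
#   depthwise conv -> GroupNorm -> Att_1 -> ELU -> pointwise conv -> GroupNorm
#   -> ELU -> residual add with the block input -> Att_2
# with Att_1 = spatial and Att_2 = channel attention by default. Setting both
# attention slots to "none" yields the plain depthwise-separable ("dsc")
# block; type "conv" replaces the depthwise/pointwise pair with a single
# standard 3x3x3 convolution and carries no attention slots (the baseline
# used for the lightweight comparison). When in/out channel counts differ the
# identity path goes through a 1x1x1 projection convolution. Convolutions
# immediately followed by GroupNorm carry no bias (the normalization absorbs
# it), which keeps parameter counts reproducible.

#' Block configuration
#'
#' @param in_channels,out_channels channel counts of the block.
#' @param type one of `"dspc"`, `"dsc"` (both attention slots off) or
#'   `"conv"` (standard 3x3x3 convolution baseline).
#' @param depthwise_kernel odd spatial kernel of the depthwise convolution.
#' @param att1,att2 attention slot contents: one of `"none"`, `"spatial"`,
#'   `"channel"`, `"coordinate"`, `"cbam"`.
#' @param spatial_kernel odd kernel of spatial-attention gates.
#' @param groupnorm_groups requested GroupNorm group count (clamped to the
#'   largest divisor of the channel count).
#' @param channel_reduction bottleneck ratio of channel/coordinate attention.
#' @return a list of class `nl_block_config`.
#' @export
block_config <- function(in_channels, out_channels, type = "dspc",
                         depthwise_kernel = 3, att1 = "spatial",
                         att2 = "channel", spatial_kernel = 7,
                         groupnorm_groups = 8, channel_reduction = 4) {
  type <- match.arg(type, c("dspc", "dsc", "conv"))
  if (depthwise_kernel %% 2 != 1)
    stop("depthwise_kernel must be odd, got ", depthwise_kernel)
  if (channel_reduction < 1) stop("channel_reduction must be >= 1")
  atts <- c("none", "spatial", "channel", "coordinate", "cbam")
  att1 <- match.arg(att1, atts)
  att2 <- match.arg(att2, atts)
  if (type %in% c("dsc", "conv")) att1 <- att2 <- "none"
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 type = type, depthwise_kernel = depthwise_kernel,
                 att1 = att1, att2 = att2, spatial_kernel = spatial_kernel,
                 groupnorm_groups = groupnorm_groups,
                 channel_reduction = channel_reduction),
            class = "nl_block_config")
}

#' Build a convolution block
#'
#' @param cfg an [block_config()] object.
#' @param name layer-name prefix used in complexity breakdowns.
#' @return a mutable block object usable with the internal forward/backward
#'   machinery.
#' @export
build_block <- function(cfg, name = "block") {
  stopifnot(inherits(cfg, "nl_block_config"))
  cin <- cfg$in_channels
  cout <- cfg$out_channels
  mk_att <- function(type, channels, suffix)
    attention_layer(type, channels, cfg$channel_reduction, cfg$spatial_kernel,
                    paste0(name, ".", suffix))
  if (cfg$type == "conv") {
    layers <- list(
      conv = conv3d_layer(cin, cout, cfg$depthwise_kernel, bias = FALSE,
                          name = paste0(name, ".conv")),
      gn = groupnorm_layer(cout, cfg$groupnorm_groups,
                           name = paste0(name, ".gn")),
      elu = elu_layer(name = paste0(name, ".elu")))
  } else {
    layers <- list(
      dw = conv3d_layer(cin, cin, cfg$depthwise_kernel, groups = cin,
                        bias = FALSE, name = paste0(name, ".dw")),
      gn1 = groupnorm_layer(cin, cfg$groupnorm_groups,
                            name = paste0(name, ".gn1")),
      att1 = mk_att(cfg$att1, cin, "att1"),
      elu1 = elu_layer(name = paste0(name, ".elu1")),
      pw = conv3d_layer(cin, cout, 1, bias = FALSE,
                        name = paste0(name, ".pw")),
      gn2 = groupnorm_layer(cout, cfg$groupnorm_groups,
                            name = paste0(name, ".gn2")),
      elu2 = elu_layer(name = paste0(name, ".elu2")),
      att2 = mk_att(cfg$att2, cout, "att2"))
  }
  proj <- if (cin != cout)
    conv3d_layer(cin, cout, 1, bias = TRUE, name = paste0(name, ".proj"))
  new_layer("nl_block", params = list(), grads = list(), cfg = cfg,
            layers = layers, proj = proj, name = name)
}

leaf_layers.nl_block <- function(obj)
  leaf_layers(c(unname(obj$layers), list(obj$proj)))

ly_forward.nl_block <- function(layer, x, training = FALSE) {
  cfg <- layer$cfg
  if (n_channels(x) != cfg$in_channels)
    stop("block '", layer$name, "': expected ", cfg$in_channels,
         " input channels, got ", n_channels(x))
  L <- layer$layers
  skip <- if (is.null(layer$proj)) x else ly_forward(layer$proj, x, training)
  if (cfg$type == "conv") {
    h <- ly_forward(L$gn, ly_forward(L$conv, x, training), training)
    out <- skip + ly_forward(L$elu, h, training)
  } else {
    h <- ly_forward(L$gn1, ly_forward(L$dw, x, training), training)
    if (!is.null(L$att1)) h <- ly_forward(L$att1, h, training)
    h <- ly_forward(L$elu1, h, training)
    h <- ly_forward(L$gn2, ly_forward(L$pw, h, training), training)
    h <- ly_forward(L$elu2, h, training)
    out <- skip + h
    if (!is.null(L$att2)) out <- ly_forward(L$att2, out, training)
  }
  out
}

ly_backward.nl_block <- function(layer, gy) {
  cfg <- layer$cfg
  L <- layer$layers
  if (cfg$type == "conv") {
    g <- ly_backward(L$gn, ly_backward(L$elu, gy))
    gx <- ly_backward(L$conv, g)
    gskip <- gy
  } else {
    if (!is.null(L$att2)) gy <- ly_backward(L$att2, gy)
    g <- ly_backward(L$elu2, gy)
    g <- ly_backward(L$pw, ly_backward(L$gn2, g))
    g <- ly_backward(L$elu1, g)
    if (!is.null(L$att1)) g <- ly_backward(L$att1, g)
    gx <- ly_backward(L$dw, ly_backward(L$gn1, g))
    gskip <- gy
  }
  if (is.null(layer$proj)) gx + gskip
  else gx + ly_backward(layer$proj, gskip)
}

#' Apply a DSPC block to a feature map
#'
#' Functional convenience wrapper: builds a block from `cfg` using the current
#' RNG stream (unless one is supplied) and runs it in evaluation mode.
#'
#' @param x feature map `[H, W, D, C]`; `C` must equal `cfg$in_channels`.
#' @param cfg an [block_config()].
#' @param block optional pre-built block from [build_block()].
#' @return feature map with `cfg$out_channels` channels, same spatial shape.
#' @export
dspc_forward <- function(x, cfg, block = NULL) {
  check_volume(x, "feature map")
  if (is.null(block)) block <- build_block(cfg)
  ly_forward(block, x, training = FALSE)
}
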