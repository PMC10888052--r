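# Analytic parameter and MAC accounting, computed from the configuration
# alone (no model needs to be built, no forward pass run). Conventions:
# 1 MAC = one multiply + one add; convolutions and the attention MLPs /
# gate convolutions are counted; ELU, GroupNorm, sigmoid and interpolation
# are excluded. GroupNorm's affine gamma/beta do count as parameters.
# The enumeration route (`count_parameters()` on a built model) serves as an
# independent cross-check in the test suite.

catt_hidden <- function(channels, reduction) {
  r <- min(max(1, reduction), channels)
  max(1L, as.integer(floor(channels / r)))
}

# rows for one attention site; `axes` = spatial extents at that site
attention_rows <- function(type, channels, reduction, kernel, axes, name) {
  vox <- prod(axes)
  hid <- catt_hidden(channels, reduction)
  switch(type,
    none = NULL,
    channel = data.frame(
      layer = name,
      params = hid * channels + hid + channels * hid + channels,
      macs = 2 * channels * hid),
    spatial = data.frame(
      layer = name, params = 2 * kernel^3 + 1, macs = 2 * kernel^3 * vox),
    coordinate = data.frame(
      layer = name,
      params = hid * channels + hid + 3 * (channels * hid + channels),
      macs = sum(axes) * channels * hid + sum(axes) * hid * channels),
    cbam = rbind(
      attention_rows("channel", channels, reduction, kernel, axes,
                     paste0(name, ".ca")),
      attention_rows("spatial", channels, reduction, kernel, axes,
                     paste0(name, ".sa"))),
    stop("unknown attention type '", type, "'"))
}

conv_row <- function(name, k, cin, cout, axes, groups = 1, bias = TRUE) {
  data.frame(layer = name,
             params = k^3 * (cin / groups) * cout + if (bias) cout else 0,
             macs = k^3 * (cin / groups) * cout * prod(axes))
}

gn_row <- function(name, channels)
  data.frame(layer = name, params = 2 * channels, macs = 0)

block_rows <- function(bc, axes, name) {
  cin <- bc$in_channels
  cout <- bc$out_channels
  rows <- if (bc$type == "conv") {
    rbind(conv_row(paste0(name, ".conv"), bc$depthwise_kernel, cin, cout,
                   axes, bias = FALSE),
          gn_row(paste0(name, ".gn"), cout))
  } else {
    rbind(conv_row(paste0(name, ".dw"), bc$depthwise_kernel, cin, cin, axes,
                   groups = cin, bias = FALSE),
          gn_row(paste0(name, ".gn1"), cin),
          attention_rows(bc$att1, cin, bc$channel_reduction,
                         bc$spatial_kernel, axes, paste0(name, ".att1")),
          conv_row(paste0(name, ".pw"), 1, cin, cout, axes, bias = FALSE),
          gn_row(paste0(name, ".gn2"), cout),
          attention_rows(bc$att2, cout, bc$channel_reduction,
                         bc$spatial_kernel, axes, paste0(name, ".att2")))
  }
  if (cin != cout)
    rows <- rbind(rows, conv_row(paste0(name, ".proj"), 1, cin, cout, axes))
  rows
}

#' Analytic complexity report
#'
#' Walks the architecture described by `cfg` and tallies learnable parameters
#' and multiply-accumulate operations per layer at the given input shape.
#'
#' @param cfg a [model_config()].
#' @param input_shape integer vector `(H, W, D)`; must be divisible by
#'   `2^levels`.
#' @return list of class `nl_complexity_report` with `breakdown` (data frame:
#'   layer, params, macs), `total_params`, `total_macs`, `input_shape`.
#' @export
model_complexity <- function(cfg, input_shape = c(192, 192, 128)) {
  stopifnot(inherits(cfg, "nlinet_config"))
  axes0 <- as.numeric(input_shape)
  check_divisible(c(axes0, 1), cfg$levels)
  L <- cfg$levels
  bc <- function(cin, cout) model_block_cfg(cfg, cin, cout)
  at_scale <- function(i) axes0 / 2^i
  rows <- rbind(
    conv_row("stem.conv", 3, cfg$input_channels, cfg$stem_channels, axes0,
             bias = FALSE),
    gn_row("stem.gn", cfg$stem_channels),
    conv_row("stem.proj", 1, cfg$input_channels, cfg$stem_channels, axes0))
  if (cfg$use_mfp) {
    for (i in seq_len(L)) {
      target <- stream_width(cfg, i)
      widths <- channel_ramp(cfg$input_channels, target, i)
      cins <- c(cfg$input_channels, widths[-i])
      for (j in seq_len(i))
        rows <- rbind(rows, block_rows(bc(cins[j], widths[j]), at_scale(i),
                                       paste0("mfp", i, ".b", j)))
      rows <- rbind(rows, attention_rows(cfg$skip_attention, target,
                                         bc(1, 1)$channel_reduction,
                                         bc(1, 1)$spatial_kernel,
                                         at_scale(i),
                                         paste0("enc", i, ".skipatt")))
    }
  }
  for (i in seq_len(L)) {
    sw <- stream_width(cfg, i)
    cin <- if (cfg$use_mfp) 2 * sw else sw
    rows <- rbind(rows, block_rows(bc(cin, cfg$encoder_channels[i]),
                                   at_scale(i), paste0("enc", i)))
  }
  for (i in seq_len(L)) {
    sw <- stream_width(cfg, i)
    rows <- rbind(rows,
                  attention_rows(cfg$skip_attention, sw,
                                 bc(1, 1)$channel_reduction,
                                 bc(1, 1)$spatial_kernel, at_scale(i - 1),
                                 paste0("dec", i, ".skipatt")))
    up_ch <- if (i == L) cfg$encoder_channels[L] else cfg$decoder_channels[i + 1]
    rows <- rbind(rows, block_rows(bc(up_ch + sw, cfg$decoder_channels[i]),
                                   at_scale(i - 1), paste0("dec", i)))
  }
  rows <- rbind(rows, conv_row("head", 1, cfg$decoder_channels[1],
                               cfg$output_channels, axes0))
  structure(list(breakdown = rows,
                 total_params = sum(rows$params),
                 total_macs = sum(rows$macs),
                 input_shape = input_shape),
            class = "nl_complexity_report")
}

#' @export
print.nl_complexity_report <- function(x, ...) {
  cat(sprintf("Complexity at input %s: %s parameters, %s MACs\n",
              paste(x$input_shape, collapse = "x"),
              format(x$total_params, big.mark = ","),
              format(x$total_macs, big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters by enumeration
#'
#' Enumerates every parameter array of a built model; independent of the
#' analytic bookkeeping in [model_complexity()].
#'
#' @param model a built model (or any block / layer).
#' @return integer count of learnable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(leaf_layers(model),
             function(l) sum(vapply(l$params, length, 1L)), 1))
}

#' Analytic MAC count
#'
#' @param model a built model.
#' @param input_shape `(H, W, D)` at which to count.
#' @return numeric MAC count.
#' @export
count_macs <- function(model, input_shape)
  model_complexity(model$cfg, input_shape)$total_macs

#' Compare two configurations
#'
#' Builds the analytic complexity reports of two configurations and reports
#' the parameter and MAC ratios a/b together with both breakdowns. Used for
#' the lightweight comparison: the same topology built with DSPC blocks
#' versus standard 3x3x3 convolution blocks.
#'
#' @param cfg_a,cfg_b two [model_config()]s.
#' @param input_shape `(H, W, D)` for the MAC counts.
#' @param quiet suppress the printed report.
#' @return list with `param_ratio`, `mac_ratio` and the two reports.
#' @export
compare_configs <- function(cfg_a, cfg_b, input_shape = c(192, 192, 128),
                            quiet = FALSE) {
  ra <- model_complexity(cfg_a, input_shape)
  rb <- model_complexity(cfg_b, input_shape)
  out <- list(param_ratio = ra$total_params / rb$total_params,
              mac_ratio = ra$total_macs / rb$total_macs,
              report_a = ra, report_b = rb)
  if (!quiet) {
    cat(sprintf("params: %s vs %s  ratio %.4f\n",
                format(ra$total_params, big.mark = ","),
                format(rb$total_params, big.mark = ","), out$param_ratio))
    cat(sprintf("MACs:   %s vs %s  ratio %.4f (input %s)\n",
                format(ra$total_macs, big.mark = ","),
                format(rb$total_macs, big.mark = ","), out$mac_ratio,
                paste(input_shape, collapse = "x")))
    cat("Assumptions: channel plan per configuration; 1 MAC = multiply+add;\n",
        "ELU/GroupNorm/sigmoid/interpolation excluded from MACs;\n",
        "convolutions before GroupNorm are bias-free.\n", sep = "")
  }
  out
}

#' Reference lightweight comparison
#'
#' The full-scale reference configuration built with DSPC blocks versus the
#' identical topology with standard 3x3x3 convolution blocks (attention slots
#' removed).
#'
#' @inheritParams compare_configs
#' @param cfg optional base configuration; defaults to [model_config()]'s
#'   reference channel plan.
#' @export
lightweight_comparison <- function(cfg = model_config(),
                                   input_shape = c(192, 192, 128),
                                   quiet = FALSE) {
  cfg_std <- cfg
  cfg_std$block <- utils::modifyList(cfg$block %||% list(),
                                     list(type = "conv"))
  compare_configs(cfg, cfg_std, input_shape, quiet = quiet)
}
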