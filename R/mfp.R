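# Multiple Feature Pyramid paths. Path i downsamples the raw multi-sequence
# input by 1/2^i with trilinear interpolation and then applies i chained DSPC
# blocks whose channel widths ramp geometrically from the input width to the
# path's target width. Paths are mutually independent: each one sees only the
# raw input.

#' MFP configuration
#'
#' @param num_paths number of pyramid paths (path `i` works at scale `1/2^i`).
#' @param input_channels channels of the raw input (MRI sequences).
#' @param per_path_out_channels integer vector, length `num_paths`: output
#'   width of each path. Conventionally the encoder stream width at the same
#'   level, so that concatenation doubles the channel count.
#' @param block [block_config()]-style template options applied to every block
#'   (channel counts are filled in per block).
#' @return list of class `nl_mfp_config`.
#' @export
mfp_config <- function(num_paths = 5, input_channels = 4,
                       per_path_out_channels, block = list()) {
  if (num_paths < 1) stop("num_paths must be >= 1")
  if (length(per_path_out_channels) != num_paths)
    stop("per_path_out_channels must have length num_paths")
  structure(list(num_paths = num_paths, input_channels = input_channels,
                 per_path_out_channels = as.integer(per_path_out_channels),
                 block = block),
            class = "nl_mfp_config")
}

# geometric channel ramp from `from` to `to` in `n` steps, final step exact
channel_ramp <- function(from, to, n) {
  if (n == 1) return(as.integer(to))
  r <- (to / from)^(seq_len(n) / n)
  w <- pmax(1L, as.integer(round(from * r)))
  w[n] <- as.integer(to)
  w
}

mfp_block_cfg <- function(cfg, cin, cout) {
  do.call(block_config, c(list(in_channels = cin, out_channels = cout),
                          cfg$block))
}

build_mfp_path <- function(i, cfg, name = paste0("mfp", i)) {
  widths <- channel_ramp(cfg$input_channels, cfg$per_path_out_channels[i], i)
  cins <- c(cfg$input_channels, widths[-i])
  blocks <- vector("list", i)
  for (j in seq_len(i))
    blocks[[j]] <- build_block(mfp_block_cfg(cfg, cins[j], widths[j]),
                               name = paste0(name, ".b", j))
  new_layer("nl_mfp_path", params = list(), grads = list(), i = i,
            resize = resize_layer(1 / 2^i, paste0(name, ".down")),
            blocks = blocks, name = name)
}

leaf_layers.nl_mfp_path <- function(obj) leaf_layers(obj$blocks)

check_divisible <- function(dims, i) {
  f <- 2^i
  bad <- which(dims[1:3] %% f != 0)
  if (length(bad))
    stop("spatial axis ", paste(c("H", "W", "D")[bad], collapse = ", "),
         " (length ", paste(dims[bad], collapse = ", "),
         ") not divisible by 2^", i)
}

ly_forward.nl_mfp_path <- function(layer, x, training = FALSE) {
  check_divisible(dim(x), layer$i)
  h <- ly_forward(layer$resize, x, training)
  for (b in layer$blocks) h <- ly_forward(b, h, training)
  h
}

ly_backward.nl_mfp_path <- function(layer, gy) {
  for (b in rev(layer$blocks)) gy <- ly_backward(b, gy)
  ly_backward(layer$resize, gy)
}

#' Run one MFP path
#'
#' Downsamples the raw input by `1/2^i` (trilinear, half-pixel centers) and
#' applies `i` chained DSPC blocks.
#'
#' @param x raw input volume `[H, W, D, C]`, spatial dims divisible by `2^i`.
#' @param i path index, `1 <= i <= cfg$num_paths`.
#' @param cfg an [mfp_config()].
#' @param path optional pre-built path object.
#' @return feature map at scale `1/2^i` with the path's configured width.
#' @export
mfp_path_forward <- function(x, i, cfg, path = NULL) {
  check_volume(x, "input")
  if (i < 1 || i > cfg$num_paths) stop("path index out of range")
  if (is.null(path)) path <- build_mfp_path(i, cfg)
  ly_forward(path, x, training = FALSE)
}

#' Run all MFP paths
#'
#' @inheritParams mfp_path_forward
#' @param paths optional list of pre-built paths.
#' @return list of `cfg$num_paths` feature maps, the i-th at scale `1/2^i`.
#' @export
mfp_forward_all <- function(x, cfg, paths = NULL) {
  check_volume(x, "input")
  if (is.null(paths))
    paths <- lapply(seq_len(cfg$num_paths), build_mfp_path, cfg = cfg)
  lapply(paths, ly_forward, x = x, training = FALSE)
}
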