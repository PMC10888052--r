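# Full N-shaped network: input stem, MFP paths, encoder with attention-gated
# pyramid fusion, decoder with attention-gated skips, sigmoid output head.
#
# Stem (level 0):   F0 = ELU(proj(x) + GroupNorm(Conv3(x)))
# Encoder level i:  down = resize(stream, 1/2); skip = Att(MFP_i);
#                   E_i = Block(concat(down, skip))
# Decoder step i (i = levels..1):
#                   up = resize(E_levels if i == levels else D_{i+1}, 2);
#                   skip = Att(F0 if i == 1 else E_{i-1});
#                   D_i = Block(concat(up, skip))
# Head:             probs = sigmoid(Conv1(D_1))
# The decoder loop ends at full resolution, so the head output matches the
# input resolution; the three output channels are independent sigmoid
# probabilities for the nested sub-regions (ET, TC, WT).

#' Model configuration
#'
#' Every architectural choice lives here, so each ablation variant (attention
#' slot contents, skip attention, block type, MFP on/off) is constructible
#' from configuration alone.
#'
#' @param levels number of encoder/decoder levels.
#' @param stem_channels width of the stem stream.
#' @param encoder_channels integer vector (length `levels`): encoder output
#'   widths per level.
#' @param decoder_channels optional integer vector (length `levels`): decoder
#'   output width at step `i` (scale `1/2^(i-1)`). Default mirrors the
#'   encoder: `c(stem_channels, encoder_channels[1:(levels-1)])`.
#' @param input_channels number of MRI sequences.
#' @param output_channels one sigmoid channel per tumor sub-region (ET/TC/WT).
#' @param skip_attention attention applied on skip features before
#'   concatenation: `"none"`, `"spatial"`, `"channel"`, `"coordinate"`,
#'   `"cbam"`.
#' @param block block template options (see [block_config()]), channel counts
#'   filled per site.
#' @param use_mfp logical; `FALSE` removes the MFP paths (the plain
#'   encoder-decoder ablation) and feeds the encoder blocks the downsampled
#'   stream alone.
#' @param seed integer seed for weight initialization.
#' @return list of class `nlinet_config`.
#' @export
model_config <- function(levels = 5, stem_channels = 32,
                         encoder_channels = c(64, 128, 256, 320, 384),
                         decoder_channels = NULL, input_channels = 4,
                         output_channels = 3, skip_attention = "channel",
                         block = list(), use_mfp = TRUE, seed = 42) {
  if (length(encoder_channels) != levels)
    stop("encoder_channels must have length levels = ", levels)
  stream <- c(stem_channels, encoder_channels[-levels])  # width entering level i
  if (is.null(decoder_channels)) decoder_channels <- stream
  if (length(decoder_channels) != levels)
    stop("decoder_channels must have length levels = ", levels)
  skip_attention <- match.arg(skip_attention,
                              c("none", "spatial", "channel", "coordinate",
                                "cbam"))
  structure(list(levels = levels, stem_channels = stem_channels,
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channels = as.integer(decoder_channels),
                 input_channels = input_channels,
                 output_channels = output_channels,
                 skip_attention = skip_attention, block = block,
                 use_mfp = isTRUE(use_mfp), seed = as.integer(seed)),
            class = "nlinet_config")
}

# width of the encoder stream entering level i (after downsampling)
stream_width <- function(cfg, i) {
  if (i == 1) cfg$stem_channels else cfg$encoder_channels[i - 1]
}

model_block_cfg <- function(cfg, cin, cout)
  do.call(block_config, c(list(in_channels = cin, out_channels = cout),
                          cfg$block))

#' Build the segmentation model
#'
#' @param cfg a [model_config()].
#' @return a mutable model object of class `nlinet_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "nlinet_config"))
  with_seed(cfg$seed, {
    L <- cfg$levels
    tmpl <- model_block_cfg(cfg, 1, 1)   # attention options shared with blocks
    skip_att <- function(channels, name)
      attention_layer(cfg$skip_attention, channels,
                      reduction = tmpl$channel_reduction,
                      kernel = tmpl$spatial_kernel, name = name)
    stem <- list(
      conv = conv3d_layer(cfg$input_channels, cfg$stem_channels, 3,
                          bias = FALSE, name = "stem.conv"),
      gn = groupnorm_layer(cfg$stem_channels, name = "stem.gn"),
      proj = conv3d_layer(cfg$input_channels, cfg$stem_channels, 1,
                          bias = TRUE, name = "stem.proj"),
      elu = elu_layer(name = "stem.elu"))
    mfp_cfg <- NULL
    mfp_paths <- NULL
    enc_skip <- vector("list", L)
    if (cfg$use_mfp) {
      mfp_cfg <- mfp_config(L, cfg$input_channels,
                            vapply(seq_len(L), stream_width, 1, cfg = cfg),
                            block = cfg$block)
      mfp_paths <- lapply(seq_len(L), build_mfp_path, cfg = mfp_cfg)
      for (i in seq_len(L))
        enc_skip[i] <- list(skip_att(mfp_cfg$per_path_out_channels[i],
                                     paste0("enc", i, ".skipatt")))
    }
    enc_blocks <- vector("list", L)
    for (i in seq_len(L)) {
      sw <- stream_width(cfg, i)
      cin <- if (cfg$use_mfp) 2L * sw else sw
      enc_blocks[[i]] <- build_block(
        model_block_cfg(cfg, cin, cfg$encoder_channels[i]),
        name = paste0("enc", i))
    }
    dec_skip <- vector("list", L)
    dec_blocks <- vector("list", L)
    for (i in seq_len(L)) {
      sw <- stream_width(cfg, i)   # skip source width at decoder step i
      dec_skip[i] <- list(skip_att(sw, paste0("dec", i, ".skipatt")))
      up_ch <- if (i == L) cfg$encoder_channels[L] else cfg$decoder_channels[i + 1]
      dec_blocks[[i]] <- build_block(
        model_block_cfg(cfg, up_ch + sw, cfg$decoder_channels[i]),
        name = paste0("dec", i))
    }
    head <- conv3d_layer(cfg$decoder_channels[1], cfg$output_channels, 1,
                         bias = TRUE, name = "head")
    # rare-foreground prior: start sigmoid outputs near 0.12 rather than 0.5
    # so small sub-regions are not flooded by false positives early on
    head$params$bias[] <- -2
    down <- resize_layer(1 / 2, "down")
    up <- resize_layer(2, "up")
    model <- new_layer("nlinet_model", params = list(), grads = list(),
                       cfg = cfg, stem = stem, mfp_cfg = mfp_cfg,
                       mfp_paths = mfp_paths, enc_skip = enc_skip,
                       enc_blocks = enc_blocks, dec_skip = dec_skip,
                       dec_blocks = dec_blocks, head = head,
                       down_layers = lapply(seq_len(L), function(i)
                         resize_layer(1 / 2, paste0("down", i))),
                       up_layers = lapply(seq_len(L), function(i)
                         resize_layer(2, paste0("up", i))))
    model
  })
}

leaf_layers.nlinet_model <- function(obj) {
  leaf_layers(c(list(obj$stem$conv, obj$stem$gn, obj$stem$proj),
                obj$mfp_paths %||% list(), obj$enc_skip, obj$enc_blocks,
                obj$dec_skip, obj$dec_blocks, list(obj$head)))
}

check_model_input <- function(model, x) {
  check_volume(x, "input volume")
  cfg <- model$cfg
  if (n_channels(x) != cfg$input_channels)
    stop("expected ", cfg$input_channels, " input channels, got ",
         n_channels(x))
  check_divisible(dim(x), cfg$levels)
}

#' Forward pass
#'
#' @param model a built model.
#' @param x input volume `[H, W, D, C]`, spatial dims divisible by
#'   `2^levels`.
#' @param training cache intermediates for a subsequent backward pass.
#' @return probability volume `[H, W, D, output_channels]`, values in (0, 1).
#' @export
model_forward <- function(model, x, training = FALSE) {
  check_model_input(model, x)
  cfg <- model$cfg
  L <- cfg$levels
  S <- model$stem
  h <- ly_forward(S$gn, ly_forward(S$conv, x, training), training)
  f0 <- ly_forward(S$elu, ly_forward(S$proj, x, training) + h, training)
  mfp <- NULL
  if (cfg$use_mfp)
    mfp <- lapply(model$mfp_paths, ly_forward, x = x, training = training)
  enc <- vector("list", L)
  stream <- f0
  for (i in seq_len(L)) {
    dn <- ly_forward(model$down_layers[[i]], stream, training)
    if (cfg$use_mfp) {
      sk <- mfp[[i]]
      if (!is.null(model$enc_skip[[i]]))
        sk <- ly_forward(model$enc_skip[[i]], sk, training)
      dn <- abind4(dn, sk)
    }
    enc[[i]] <- ly_forward(model$enc_blocks[[i]], dn, training)
    stream <- enc[[i]]
  }
  dec_prev <- NULL
  for (i in rev(seq_len(L))) {
    src <- if (i == L) enc[[L]] else dec_prev
    upf <- ly_forward(model$up_layers[[i]], src, training)
    sk <- if (i == 1) f0 else enc[[i - 1]]
    if (!is.null(model$dec_skip[[i]]))
      sk <- ly_forward(model$dec_skip[[i]], sk, training)
    dec_prev <- ly_forward(model$dec_blocks[[i]],
                           abind4(upf, sk), training)
  }
  logits <- ly_forward(model$head, dec_prev, training)
  probs <- sigmoid(logits)
  if (training) model$probs <- probs
  probs
}

# concatenate along the channel axis
abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  if (any(da[1:3] != db[1:3]))
    stop("channel concat: spatial shapes differ (",
         paste(da[1:3], collapse = "x"), " vs ",
         paste(db[1:3], collapse = "x"), ")")
  array(c(a, b), dim = c(da[1:3], da[4] + db[4]))
}

split4 <- function(g, c1) {
  d <- dim(g)
  ga <- array(g[, , , seq_len(c1), drop = FALSE], dim = c(d[1:3], c1))
  gb <- array(g[, , , c1 + seq_len(d[4] - c1), drop = FALSE],
              dim = c(d[1:3], d[4] - c1))
  list(ga, gb)
}

# Reverse pass: `gprobs` is dLoss/dprobs; parameter gradients accumulate in
# the leaf layers. Returns the gradient with respect to the model input
# (useful for finite-difference validation).
model_backward <- function(model, gprobs) {
  cfg <- model$cfg
  L <- cfg$levels
  p <- model$probs
  glogits <- gprobs * p * (1 - p)
  gdec <- ly_backward(model$head, glogits)
  genc <- vector("list", L)       # accumulated grads for encoder outputs
  gf0 <- NULL
  add_to <- function(cur, g) if (is.null(cur)) g else cur + g
  # decoder: computation order was i = L..1; reverse it (i = 1..L)
  for (i in seq_len(L)) {
    blk <- model$dec_blocks[[i]]
    up_ch <- if (i == L) cfg$encoder_channels[L] else cfg$decoder_channels[i + 1]
    gcat <- ly_backward(blk, gdec)
    sp <- split4(gcat, up_ch)
    gsk <- sp[[2]]
    if (!is.null(model$dec_skip[[i]]))
      gsk <- ly_backward(model$dec_skip[[i]], gsk)
    if (i == 1) gf0 <- add_to(gf0, gsk)
    else genc[[i - 1]] <- add_to(genc[[i - 1]], gsk)
    gup <- ly_backward(model$up_layers[[i]], sp[[1]])
    if (i == L) {
      genc[[L]] <- add_to(genc[[L]], gup)
    } else {
      gdec <- gup                  # gradient for D_{i+1}, consumed next turn
    }
  }
  # encoder: computation order was i = 1..L; reverse it
  gmfp <- vector("list", L)
  for (i in rev(seq_len(L))) {
    gcat <- ly_backward(model$enc_blocks[[i]], genc[[i]])
    if (cfg$use_mfp) {
      sw <- stream_width(cfg, i)
      sp <- split4(gcat, sw)
      gsk <- sp[[2]]
      if (!is.null(model$enc_skip[[i]]))
        gsk <- ly_backward(model$enc_skip[[i]], gsk)
      gmfp[[i]] <- gsk
      gdn <- sp[[1]]
    } else {
      gdn <- gcat
    }
    gstream <- ly_backward(model$down_layers[[i]], gdn)
    if (i == 1) gf0 <- add_to(gf0, gstream)
    else genc[[i - 1]] <- add_to(genc[[i - 1]], gstream)
  }
  gx <- NULL
  if (cfg$use_mfp)
    for (i in seq_len(L))
      gx <- add_to(gx, ly_backward(model$mfp_paths[[i]], gmfp[[i]]))
  # stem
  S <- model$stem
  ge <- ly_backward(S$elu, gf0)
  gx <- add_to(gx, ly_backward(S$proj, ge))
  gx <- add_to(gx, ly_backward(S$conv, ly_backward(S$gn, ge)))
  gx
}

#' Thresholded prediction
#'
#' Runs the forward pass and thresholds the sigmoid probabilities; ties
#' (`p == threshold`) map to 1 so the discretization is deterministic.
#'
#' @inheritParams model_forward
#' @param threshold probability cutoff, strictly inside (0, 1).
#' @param enforce_nesting if `TRUE`, post-process the three masks so the
#'   nesting ET within TC within WT holds (intersection from the outside in).
#' @return list with `probabilities` and binary `masks`, both
#'   `[H, W, D, output_channels]` (channel order ET, TC, WT).
#' @export
model_predict <- function(model, x, threshold = 0.5, enforce_nesting = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  probs <- model_forward(model, x, training = FALSE)
  masks <- (probs >= threshold) * 1
  if (enforce_nesting && dim(masks)[4] == 3) {
    masks[, , , 2] <- masks[, , , 2] * masks[, , , 3]   # TC within WT
    masks[, , , 1] <- masks[, , , 1] * masks[, , , 2]   # ET within TC
  }
  list(probabilities = probs, masks = masks)
}

#' Extract / restore model weights
#'
#' `model_state()` returns all learnable arrays as a named list;
#' `load_state()` writes such a list back into a model of the same
#' architecture. Checkpoints are these states serialized with `saveRDS()`.
#'
#' @param model a built model.
#' @return named list of parameter lists, one entry per leaf layer.
#' @export
model_state <- function(model) lapply(leaf_layers(model), function(l) l$params)

#' @rdname model_state
#' @param state a list previously produced by `model_state()`.
#' @export
load_state <- function(model, state) {
  leaves <- leaf_layers(model)
  if (!identical(names(leaves), names(state)))
    stop("checkpoint layout does not match the model architecture")
  for (nm in names(leaves)) leaves[[nm]]$params <- state[[nm]]
  invisible(model)
}

#' @rdname model_state
#' @param path file path of the checkpoint.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$cfg, state = model_state(model)), path)
  invisible(path)
}

#' @rdname model_state
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  load_state(model, ck$state)
  model
}
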