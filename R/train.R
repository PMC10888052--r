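# Training/evaluation loop. Optimizer: AdamW (decoupled weight decay).
# Full-scale defaults follow the training protocol the architecture is meant
# for: learning rate 1e-4, weight decay 1e-5, batch size 1, 200 epochs,
# constant learning rate, best-validation-Dice checkpoint selection. The
# desk-scale test profile (tiny model, tiny phantoms, 20 epochs) uses
# learning rate 1e-3: over a ~200-step schedule an Adam-style update moves
# each weight by roughly lr per step, so 1e-4 cannot traverse the
# initialization noise at that scale; see the methods vignette.

#' Training configuration
#'
#' @param lr initial learning rate (constant schedule).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size cases per optimizer step (1: per-case weights for the
#'   weighted cross-entropy are exact).
#' @param epochs training epochs.
#' @param loss `"dice"`, `"dice_ce"` (Dice + unweighted per-region binary
#'   cross-entropy) or `"dice_wce"` (the combo loss).
#' @param seed seed controlling shuffling.
#' @param checkpoint optional path: best-validation-Dice weights are saved
#'   there.
#' @param log optional path of a JSON-lines per-epoch log.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-5, batch_size = 1,
                         epochs = 200, loss = "dice_wce", seed = 1,
                         checkpoint = NULL, log = NULL) {
  if (lr <= 0 || weight_decay < 0) stop("lr must be > 0 and weight_decay >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  loss <- match.arg(loss, c("dice", "dice_ce", "dice_wce"))
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = batch_size, epochs = as.integer(epochs),
                 loss = loss, seed = as.integer(seed),
                 checkpoint = checkpoint, log = log),
            class = "train_config")
}

adamw_new <- function(leaves) {
  lapply(leaves, function(l) lapply(l$params, function(p) {
    list(m = zero_like(list(p))[[1]], v = zero_like(list(p))[[1]])
  }))
}

adamw_step <- function(opt, leaves, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(leaves)) {
    l <- leaves[[nm]]
    for (pn in names(l$params)) {
      g <- l$grads[[pn]]
      st <- opt[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      opt[[nm]][[pn]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      l$params[[pn]] <- l$params[[pn]] - lr * (upd + wd * l$params[[pn]])
    }
  }
  opt
}

train_step <- function(model, case, loss_kind) {
  p <- model_forward(model, case$sequences, training = TRUE)
  lv <- training_loss(p, case$labels, loss_kind)
  model_backward(model, lv$grad)
  lv
}

mean_val_dice <- function(model, cases) {
  if (!length(cases)) return(NA_real_)
  ds <- vapply(cases, function(cs) {
    pr <- model_predict(model, cs$sequences)
    gt <- subregion_masks(cs$labels)$masks
    mean(vapply(1:3, function(k) {
      as.numeric(dice(confusion_counts(pr$masks[, , , k], gt[, , , k])))
    }, 1))
  }, 1)
  mean(ds)
}

#' Train a model
#'
#' Seeded, CPU-based training at batch size 1. Per-epoch mean training loss
#' and validation Dice are logged; the weights with the best validation Dice
#' are retained (and written to `cfg$checkpoint` when set). A non-finite loss
#' aborts with a diagnostic.
#'
#' @param model a built model (modified in place).
#' @param train_cases,val_cases lists of `nl_case` objects (already
#'   preprocessed; no augmentation is applied at validation time).
#' @param cfg a [train_config()].
#' @param augment_fn optional function(case, seed) applied to each training
#'   case each epoch (e.g. a wrapper around [augment()]).
#' @param verbose print per-epoch progress.
#' @return list with `history` (data frame: epoch, loss, val_dice),
#'   `best_state`, `best_epoch`, `best_val_dice`.
#' @export
train <- function(model, train_cases, val_cases = list(),
                  cfg = train_config(), augment_fn = NULL, verbose = FALSE) {
  if (!length(train_cases)) stop("empty training set")
  leaves <- leaf_layers(model)
  opt <- adamw_new(leaves)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_dice = numeric())
  best <- list(state = model_state(model), dice = -Inf, epoch = 0L)
  step <- 0L
  log_con <- if (!is.null(cfg$log)) file(cfg$log, open = "w")
  on.exit(if (!is.null(log_con)) close(log_con))
  for (epoch in seq_len(cfg$epochs)) {
    order_ <- with_seed(derive_seed(cfg$seed, epoch),
                        sample(seq_along(train_cases)))
    losses <- numeric(0)
    for (ci in order_) {
      case <- train_cases[[ci]]
      if (!is.null(augment_fn))
        case <- augment_fn(case, derive_seed(cfg$seed, epoch, ci))
      zero_grads(model)
      lv <- train_step(model, case, cfg$loss)
      if (!is.finite(lv$total))
        stop("non-finite loss at epoch ", epoch, ", case ", case$case_id,
             " (dice ", lv$dice_part, ", wce ", lv$wce_part, ")")
      step <- step + 1L
      opt <- adamw_step(opt, leaves, cfg$lr, cfg$weight_decay, step)
      losses <- c(losses, lv$total)
    }
    vd <- mean_val_dice(model, val_cases)
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_dice = vd))
    if (!is.na(vd) && vd > best$dice)
      best <- list(state = model_state(model), dice = vd, epoch = epoch)
    if (!is.null(log_con))
      writeLines(jsonlite::toJSON(list(epoch = epoch, loss = mean(losses),
                                       val_dice = vd), auto_unbox = TRUE,
                                  digits = NA), log_con)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %s", epoch,
                      mean(losses),
                      if (is.na(vd)) "-" else sprintf("%.4f", vd)))
  }
  if (is.infinite(best$dice))
    best <- list(state = model_state(model), dice = NA_real_,
                 epoch = cfg$epochs)
  load_state(model, best$state)
  if (!is.null(cfg$checkpoint)) save_checkpoint(model, cfg$checkpoint)
  list(history = history, best_state = best$state, best_epoch = best$epoch,
       best_val_dice = best$dice)
}

#' Evaluate a model over cases
#'
#' @param model a built (trained) model.
#' @param cases list of `nl_case` objects.
#' @param spacing voxel spacing passed to the surface-distance metric.
#' @param out_csv optional path: writes the per-case table plus a summary
#'   mean row, values formatted to two decimals.
#' @return data frame with one row per case (per-region and mean IoU, Dice,
#'   HD95) plus a `mean` summary row.
#' @export
evaluate_cases <- function(model, cases, spacing = c(1, 1, 1),
                           out_csv = NULL) {
  rows <- lapply(cases, function(cs) {
    pr <- model_predict(model, cs$sequences)
    gt <- subregion_masks(cs$labels)
    rep_ <- evaluate_case(pr$masks, gt, spacing)
    tab <- rep_$per_region
    out <- data.frame(case_id = cs$case_id)
    for (k in seq_len(nrow(tab))) {
      r <- tab$region[k]
      out[[paste0("iou_", r)]] <- tab$iou[k]
      out[[paste0("dice_", r)]] <- tab$dice[k]
      out[[paste0("hd95_", r)]] <- tab$hd95[k]
    }
    out$iou_mean <- rep_$means[["iou"]]
    out$dice_mean <- rep_$means[["dice"]]
    out$hd95_mean <- rep_$means[["hd95"]]
    out
  })
  tab <- do.call(rbind, rows)
  summary_row <- tab[1, ]
  summary_row$case_id <- "mean"
  for (cn in names(tab)[-1]) summary_row[[cn]] <- mean(tab[[cn]])
  tab <- rbind(tab, summary_row)
  if (!is.null(out_csv)) {
    fmt <- tab
    for (cn in names(fmt)[-1]) fmt[[cn]] <- sprintf("%.2f", fmt[[cn]])
    write.csv(fmt, out_csv, row.names = FALSE)
  }
  tab
}

#' Predict and export masks for one case
#'
#' Writes one binary NIfTI mask per sub-region plus a fused BraTS-style label
#' map (ET voxels code 3, remaining TC voxels 1, remaining WT voxels 2).
#'
#' @param model a built model.
#' @param case an `nl_case`.
#' @param out_dir output directory.
#' @param threshold probability cutoff.
#' @param enforce_nesting force the nesting ET within TC within WT before
#'   fusing.
#' @return paths of the written files, invisibly.
#' @export
predict_case <- function(model, case, out_dir, threshold = 0.5,
                         enforce_nesting = TRUE) {
  pr <- model_predict(model, case$sequences, threshold, enforce_nesting)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (k in seq_along(REGIONS)) {
    img <- RNifti::asNifti(array(pr$masks[, , , k], dim = dim(case$labels)),
                           pixdim = case$spacing)
    p <- file.path(out_dir, sprintf("%s_%s.nii.gz", case$case_id, REGIONS[k]))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  fused <- fuse_masks(pr$masks)
  p <- file.path(out_dir, sprintf("%s_pred_seg.nii.gz", case$case_id))
  RNifti::writeNifti(RNifti::asNifti(fused, pixdim = case$spacing), p)
  invisible(c(paths, p))
}

# nested sub-region masks -> label map (internal codes)
fuse_masks <- function(masks) {
  d <- dim(masks)[1:3]
  lab <- array(0L, dim = d)
  lab[masks[, , , 3] > 0] <- LABEL_CODES[["ED"]]
  lab[masks[, , , 2] > 0] <- LABEL_CODES[["NCR"]]
  lab[masks[, , , 1] > 0] <- LABEL_CODES[["ET"]]
  lab
}
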