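# Sub-region masks, per-region weights and the combo loss.
#
# Ground-truth labels use the internal integer codes
#   0 background, 1 NCR (necrotic / non-enhancing core), 2 ED (edema),
#   3 ET (enhancing tumor)
# and the nested sub-regions are ET = {3}, TC = ET + NCR, WT = TC + ED.
# The loss operates on the three sub-region channels (ET, TC, WT):
#   L_combo = L_dice + L_wce
#   L_dice  = 1 - (2/|K|) * sum_k (sum_i y_ik p_ik) / (sum_i y_ik + sum_i p_ik)
#   L_wce   = -(1/N) * sum_i sum_k w_k y_ik ln(p_ik),  w_k = |WT| / |k|
# The weighted cross-entropy carries only the positive-class term, exactly as
# the weighting scheme is defined; on its own it is therefore minimized by
# p == 1 everywhere, and only the Dice term penalizes false positives. The
# test suite asserts this known degeneracy explicitly.

LABEL_CODES <- c(background = 0L, NCR = 1L, ED = 2L, ET = 3L)
REGIONS <- c("ET", "TC", "WT")

#' Nested sub-region masks from a label volume
#'
#' @param labels integer array `[H, W, D]` with values in {0, 1, 2, 3}
#'   (background, NCR, ED, ET).
#' @return list of class `subregion_masks`: `masks` is `[H, W, D, 3]` binary
#'   with channel order (ET, TC, WT); `counts` the per-region voxel counts.
#' @export
subregion_masks <- function(labels) {
  if (is.list(labels) && !is.null(labels$masks)) return(labels)
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, LABEL_CODES)
  if (length(bad))
    stop("unknown label value(s): ", paste(sort(bad), collapse = ", "))
  d <- dim(labels)
  et <- labels == LABEL_CODES[["ET"]]
  tc <- et | labels == LABEL_CODES[["NCR"]]
  wt <- tc | labels == LABEL_CODES[["ED"]]
  masks <- array(as.numeric(c(et, tc, wt)), dim = c(d, 3L),
                 dimnames = list(NULL, NULL, NULL, REGIONS))
  structure(list(masks = masks,
                 counts = c(ET = sum(et), TC = sum(tc), WT = sum(wt))),
            class = "subregion_masks")
}

#' Sub-region loss weights
#'
#' `w_k = |WT| / |k|` from the ground-truth voxel counts, computed per sample;
#' an empty sub-region gets weight 0 (it contributes no positive voxels to
#' the cross-entropy anyway, and this avoids a division by zero).
#'
#' @param masks a [subregion_masks()] object (or a label volume).
#' @return named numeric vector `(ET, TC, WT)` of class `region_weights` with
#'   attribute `counts`.
#' @export
region_weights <- function(masks) {
  masks <- subregion_masks(masks)
  counts <- masks$counts
  w <- ifelse(counts > 0, counts[["WT"]] / counts, 0)
  structure(stats::setNames(as.numeric(w), REGIONS), counts = counts,
            class = "region_weights")
}

as_region_array <- function(y) {
  if (inherits(y, "subregion_masks")) y$masks else y
}

check_py <- function(p, y) {
  if (!identical(dim(p), dim(y)))
    stop("prediction and target shapes differ: (",
         paste(dim(p), collapse = "x"), ") vs (",
         paste(dim(y), collapse = "x"), ")")
}

#' Dice loss
#'
#' `1 - (2/K) * sum_k (sum y p + eps) / (sum y + sum p + eps)` over the
#' sub-region channels. The smoothing `eps` makes an empty region with an
#' empty prediction contribute a perfect term instead of 0/0.
#'
#' @param p probability array `[H, W, D, K]` in `[0, 1]`.
#' @param y binary target of the same shape, or a [subregion_masks()].
#' @param eps smoothing constant.
#' @param grad also return the gradient with respect to `p`.
#' @return loss value (with attribute `grad` if requested).
#' @export
dice_loss <- function(p, y, eps = 1e-5, grad = FALSE) {
  y <- as_region_array(y)
  check_py(p, y)
  K <- dim(p)[4L]
  nspat <- prod(dim(p)[1:3])
  pm <- matrix(p, nrow = nspat)
  ym <- matrix(y, nrow = nspat)
  syp <- colSums(ym * pm)
  sy <- colSums(ym)
  sp_ <- colSums(pm)
  denom <- sy + sp_ + eps
  loss <- 1 - (2 / K) * sum((syp + eps) / denom)
  if (grad) {
    gm <- -(2 / K) * (sweep(ym, 2, denom, "*") -
                        matrix(rep(syp + eps, each = nspat), nrow = nspat)) /
      matrix(rep(denom^2, each = nspat), nrow = nspat)
    attr(loss, "grad") <- array(gm, dim = dim(p))
  }
  loss
}

#' Weighted cross-entropy loss
#'
#' Positive-class weighted cross-entropy, `-(1/N) sum_i sum_k w_k y ln(p)`;
#' `N` is the voxel count of the volume (not times K). Probabilities are
#' clamped to `[clamp, 1 - clamp]` before the logarithm.
#'
#' @inheritParams dice_loss
#' @param w a [region_weights()] vector (or anything coercible: numeric of
#'   length K).
#' @param clamp probability clamp for the logarithm.
#' @export
wce_loss <- function(p, y, w, clamp = 1e-7, grad = FALSE) {
  y <- as_region_array(y)
  check_py(p, y)
  K <- dim(p)[4L]
  if (length(w) != K) stop("need one weight per region channel")
  nvox <- prod(dim(p)[1:3])
  pc <- pmin(pmax(p, clamp), 1 - clamp)
  wfull <- bcast_channel(as.numeric(w), dim(p))
  loss <- -sum(wfull * y * log(pc)) / nvox
  if (grad) {
    g <- -(wfull * y / pc) / nvox
    g[p > 1 - clamp | p < clamp] <- 0   # flat outside the clamp range
    attr(loss, "grad") <- g
  }
  loss
}

#' Combo loss
#'
#' `L_dice + L_wce` with the sub-region weights computed internally from the
#' ground truth of the current sample.
#'
#' @inheritParams dice_loss
#' @param y a [subregion_masks()] object (weights need its voxel counts) or a
#'   label volume `[H, W, D]`.
#' @return list of class `loss_value` with `total`, `dice_part`, `wce_part`
#'   (and `grad` if requested).
#' @export
combo_loss <- function(p, y, eps = 1e-5, clamp = 1e-7, grad = FALSE) {
  y <- subregion_masks(y)
  w <- region_weights(y)
  dl <- dice_loss(p, y$masks, eps = eps, grad = grad)
  wl <- wce_loss(p, y$masks, w, clamp = clamp, grad = grad)
  out <- list(total = as.numeric(dl) + as.numeric(wl),
              dice_part = as.numeric(dl), wce_part = as.numeric(wl))
  if (grad) out$grad <- attr(dl, "grad") + attr(wl, "grad")
  structure(out, class = "loss_value")
}

# per-region unweighted binary cross-entropy (both terms); the "DiceCE"
# baseline of the loss comparison
bce_loss <- function(p, y, clamp = 1e-7, grad = FALSE) {
  y <- as_region_array(y)
  check_py(p, y)
  nvox <- prod(dim(p)[1:3])
  pc <- pmin(pmax(p, clamp), 1 - clamp)
  loss <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / nvox
  if (grad) {
    g <- ((1 - y) / (1 - pc) - y / pc) / nvox
    g[p > 1 - clamp | p < clamp] <- 0
    attr(loss, "grad") <- g
  }
  loss
}

# dispatch used by the training loop: "dice", "dice_ce" or "dice_wce"
training_loss <- function(p, y, kind = "dice_wce") {
  y <- subregion_masks(y)
  kind <- match.arg(kind, c("dice", "dice_ce", "dice_wce"))
  if (kind == "dice_wce") return(combo_loss(p, y, grad = TRUE))
  dl <- dice_loss(p, y$masks, grad = TRUE)
  if (kind == "dice") {
    return(structure(list(total = as.numeric(dl), dice_part = as.numeric(dl),
                          wce_part = 0, grad = attr(dl, "grad")),
                     class = "loss_value"))
  }
  ce <- bce_loss(p, y$masks, grad = TRUE)
  structure(list(total = as.numeric(dl) + as.numeric(ce),
                 dice_part = as.numeric(dl), wce_part = as.numeric(ce),
                 grad = attr(dl, "grad") + attr(ce, "grad")),
            class = "loss_value")
}
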