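# Evaluation suite: voxel-wise confusion counts, IoU and Dice, and the
# 95th-percentile Hausdorff surface distance.
#
# Surface definition: a mask voxel with at least one 6-neighbor outside the
# mask; voxels on the volume border count as surface (everything outside the
# volume is background). Directed distances are computed with an exact
# Euclidean distance transform; HD95 aggregates the two directed 95th
# percentiles with a max (the percentile substituted into the max-of-directed
# Hausdorff definition). Percentiles use linear interpolation between order
# statistics. Empty-mask conventions (flagged in every report): both masks
# empty -> iou/dice 1, hd95 0; exactly one empty -> hd95 = the volume
# diagonal sentinel.

#' Voxel-wise confusion counts
#'
#' @param P,Y binary arrays of identical shape (prediction, ground truth).
#' @return list of class `confusion_counts` with `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(P, Y) {
  if (!identical(dim(P), dim(Y)))
    stop("mask shapes differ: (", paste(dim(P), collapse = "x"), ") vs (",
         paste(dim(Y), collapse = "x"), ")")
  p <- as.logical(P)
  y <- as.logical(Y)
  structure(list(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y)),
            class = "confusion_counts")
}

#' Intersection over union
#'
#' `TP / (TP + FP + FN)`; when both masks are empty the value is undefined
#' and the convention 1.0 is returned with attribute `undefined = TRUE`.
#'
#' @param counts a [confusion_counts()] object.
#' @export
iou <- function(counts) {
  d <- counts$TP + counts$FP + counts$FN
  if (d == 0) return(structure(1, undefined = TRUE))
  counts$TP / d
}

#' Dice overlap
#'
#' `2 TP / (2 TP + FP + FN)`; both-empty convention as in [iou()].
#'
#' @inheritParams iou
#' @export
dice <- function(counts) {
  d <- 2 * counts$TP + counts$FP + counts$FN
  if (d == 0) return(structure(1, undefined = TRUE))
  2 * counts$TP / d
}

# 6-connectivity surface voxels; outside the volume counts as background
surface_mask <- function(m) {
  m <- array(as.logical(m), dim = dim(m))
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  inner <- pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  m & !inner
}

volume_diagonal <- function(dims, spacing)
  sqrt(sum((dims * spacing)^2))

directed_surface_distances <- function(from_surf, to_surf, spacing) {
  dt <- edt3d(to_surf, spacing[1], spacing[2], spacing[3])
  dt[from_surf]
}

#' 95th-percentile Hausdorff surface distance
#'
#' @param P,Y binary masks of identical shape.
#' @param spacing voxel spacing `(sx, sy, sz)` in the desired units.
#' @param percentile percentile of the directed surface distances (95 gives
#'   HD95; 100 gives the exact Hausdorff distance).
#' @param aggregate `"max"` takes the max of the two directed percentiles;
#'   `"pooled"` takes the percentile of the pooled distance set.
#' @return distance (attribute `undefined = TRUE` when a convention applied:
#'   both masks empty returns 0, exactly one empty returns the volume
#'   diagonal sentinel).
#' @export
hd95 <- function(P, Y, spacing = c(1, 1, 1), percentile = 95,
                 aggregate = c("max", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!identical(dim(P), dim(Y)))
    stop("mask shapes differ")
  np <- sum(P != 0)
  ny <- sum(Y != 0)
  if (np == 0 && ny == 0) return(structure(0, undefined = TRUE))
  if (np == 0 || ny == 0)
    return(structure(volume_diagonal(dim(P), spacing), undefined = TRUE))
  sp <- surface_mask(P)
  sy <- surface_mask(Y)
  dpy <- directed_surface_distances(sp, sy, spacing)
  dyp <- directed_surface_distances(sy, sp, spacing)
  q <- percentile / 100
  if (aggregate == "max")
    max(quantile(dpy, q, names = FALSE), quantile(dyp, q, names = FALSE))
  else
    quantile(c(dpy, dyp), q, names = FALSE)
}

#' Exact (maximum) Hausdorff surface distance
#'
#' @inheritParams hd95
#' @export
hausdorff <- function(P, Y, spacing = c(1, 1, 1))
  hd95(P, Y, spacing, percentile = 100)

#' Evaluate one case
#'
#' Per-region IoU, Dice and HD95 for the three nested sub-regions plus their
#' arithmetic means; regions where a metric is undefined by convention are
#' flagged and excluded from the means.
#'
#' @param pred,gt [subregion_masks()] objects (or binary `[H, W, D, 3]`
#'   arrays / label volumes).
#' @param spacing voxel spacing.
#' @return list of class `metrics_report` with a per-region data frame and
#'   `means`.
#' @export
evaluate_case <- function(pred, gt, spacing = c(1, 1, 1)) {
  pm <- if (inherits(pred, "subregion_masks")) pred$masks else pred
  gm <- if (inherits(gt, "subregion_masks")) gt$masks else gt
  if (length(dim(pm)) == 3L) pm <- subregion_masks(pm)$masks
  if (length(dim(gm)) == 3L) gm <- subregion_masks(gm)$masks
  if (!identical(dim(pm), dim(gm))) stop("prediction/ground-truth shape mismatch")
  rows <- lapply(seq_along(REGIONS), function(k) {
    P <- array(pm[, , , k], dim = dim(pm)[1:3])
    Y <- array(gm[, , , k], dim = dim(gm)[1:3])
    cc <- confusion_counts(P, Y)
    i <- iou(cc)
    dce <- dice(cc)
    h <- hd95(P, Y, spacing)
    data.frame(region = REGIONS[k], iou = as.numeric(i),
               dice = as.numeric(dce), hd95 = as.numeric(h),
               overlap_undefined = isTRUE(attr(i, "undefined")),
               hd95_undefined = isTRUE(attr(h, "undefined")))
  })
  tab <- do.call(rbind, rows)
  ok_ov <- !tab$overlap_undefined
  ok_hd <- !tab$hd95_undefined
  means <- c(iou = if (any(ok_ov)) mean(tab$iou[ok_ov]) else NA_real_,
             dice = if (any(ok_ov)) mean(tab$dice[ok_ov]) else NA_real_,
             hd95 = if (any(ok_hd)) mean(tab$hd95[ok_hd]) else NA_real_)
  structure(list(per_region = tab, means = means, spacing = spacing),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-region metrics:\n")
  print(transform(x$per_region, iou = round(iou, 4), dice = round(dice, 4),
                  hd95 = round(hd95, 4)), row.names = FALSE)
  cat(sprintf("Means: IoU %.4f  Dice %.4f  HD95 %.4f\n",
              x$means["iou"], x$means["dice"], x$means["hd95"]))
  invisible(x)
}
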