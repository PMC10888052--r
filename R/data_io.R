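# Case loading and preprocessing. Dataset layout follows the multi-sequence
# convention: one directory per case containing `<case>_<seq>.nii.gz` for
# each MRI sequence plus `<case>_seg.nii.gz` for the labels. Label volumes
# may use either the internal codes {0 background, 1 NCR, 2 ED, 3 ET} or the
# BraTS-style code 4 for ET, which is remapped to 3 on load.

SEQUENCE_NAMES <- c("t1", "t1ce", "t2", "flair")

#' Load one case from NIfTI files
#'
#' @param seq_paths character vector of per-sequence NIfTI paths (all
#'   co-registered, identical shape and spacing).
#' @param label_path NIfTI path of the integer label volume.
#' @param case_id optional identifier; default derived from the first path.
#' @return list of class `nl_case`: `sequences` `[H, W, D, S]`, `labels`
#'   `[H, W, D]`, `spacing`, `case_id`, `paths`.
#' @export
load_case <- function(seq_paths, label_path, case_id = NULL) {
  imgs <- lapply(seq_paths, RNifti::readNifti)
  lab <- RNifti::readNifti(label_path)
  dims <- lapply(imgs, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("sequence volumes disagree in shape")
  sp <- lapply(imgs, function(im) RNifti::pixdim(im)[1:3])
  if (max(vapply(sp, function(s) max(abs(s - sp[[1]])), 1)) > 1e-4)
    stop("sequence volumes disagree in voxel spacing")
  if (!identical(as.integer(dim(lab)), as.integer(dims[[1]])))
    stop("label volume shape differs from the sequences")
  labels <- array(as.integer(round(as.array(lab))), dim = dim(lab))
  labels[labels == 4L] <- 3L            # BraTS ET code
  bad <- setdiff(unique(as.vector(labels)), LABEL_CODES)
  if (length(bad))
    stop("unknown label code(s): ", paste(sort(bad), collapse = ", "))
  S <- length(imgs)
  d <- dims[[1]]
  seqs <- array(0, dim = c(d, S))
  for (s in seq_len(S)) seqs[, , , s] <- as.array(imgs[[s]])
  structure(list(case_id = case_id %||%
                   sub("_[^_]*\\.nii(\\.gz)?$", "", basename(seq_paths[1])),
                 sequences = seqs, labels = labels,
                 spacing = as.numeric(sp[[1]]),
                 paths = c(seq_paths, label_path)),
            class = "nl_case")
}

#' Write one case as NIfTI files
#'
#' @param case an `nl_case`.
#' @param dir output directory (one sub-directory per case is created).
#' @param seq_names file-name suffixes for the sequences.
#' @return the case directory, invisibly.
#' @export
write_case <- function(case, dir, seq_names = SEQUENCE_NAMES) {
  cdir <- file.path(dir, case$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  S <- dim(case$sequences)[4L]
  if (length(seq_names) < S) seq_names <- paste0("seq", seq_len(S))
  for (s in seq_len(S)) {
    img <- RNifti::asNifti(array(case$sequences[, , , s],
                                 dim = dim(case$sequences)[1:3]),
                           pixdim = case$spacing)
    RNifti::writeNifti(img, file.path(cdir, sprintf("%s_%s.nii.gz",
                                                    case$case_id,
                                                    seq_names[s])))
  }
  lab <- RNifti::asNifti(case$labels, pixdim = case$spacing)
  RNifti::writeNifti(lab, file.path(cdir, sprintf("%s_seg.nii.gz",
                                                  case$case_id)))
  invisible(cdir)
}

#' Load a case from its directory
#'
#' @param cdir case directory in the layout written by [write_case()].
#' @param seq_names sequence suffixes, in channel order.
#' @export
load_case_dir <- function(cdir, seq_names = SEQUENCE_NAMES) {
  id <- basename(cdir)
  paths <- file.path(cdir, sprintf("%s_%s.nii.gz", id, seq_names))
  paths <- paths[file.exists(paths)]
  if (!length(paths)) stop("no sequence files found under ", cdir)
  load_case(paths, file.path(cdir, sprintf("%s_seg.nii.gz", id)),
            case_id = id)
}

#' Z-score normalization over brain voxels
#'
#' Standardizes each sequence over its nonzero (brain) voxels to mean 0 and
#' standard deviation 1, leaving the background at exactly 0. Idempotent up
#' to floating-point error.
#'
#' @param case an `nl_case`.
#' @return the normalized case.
#' @export
zscore_normalize <- function(case) {
  S <- dim(case$sequences)[4L]
  for (s in seq_len(S)) {
    v <- case$sequences[, , , s]
    fg <- v != 0
    if (!any(fg)) stop("sequence ", s, " has no nonzero (brain) voxels")
    mu <- mean(v[fg])
    sdv <- stats::sd(v[fg])
    if (!is.finite(sdv) || sdv < 1e-12)
      stop("sequence ", s, " has constant foreground (zero variance)")
    v[fg] <- (v[fg] - mu) / sdv
    case$sequences[, , , s] <- v
  }
  case
}

# in-plane rotation about the through-plane (D) axis; bilinear for images,
# nearest for labels; out-of-bounds samples become background 0
rotate_inplane <- function(vol, angle_deg, nearest = FALSE) {
  d <- dim(vol)
  H <- d[1]; W <- d[2]
  th <- angle_deg * pi / 180
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  gh <- rep(seq_len(H), times = W) - ch
  gw <- rep(seq_len(W), each = H) - cw
  src_h <- cos(th) * gh + sin(th) * gw + ch
  src_w <- -sin(th) * gh + cos(th) * gw + cw
  if (nearest) {
    ih <- round(src_h); iw <- round(src_w)
    ok <- ih >= 1 & ih <= H & iw >= 1 & iw <= W
    idx <- ifelse(ok, ih + (iw - 1) * H, NA_integer_)
    apply_plane <- function(plane) {
      out <- numeric(H * W)
      out[ok] <- plane[idx[ok]]
      out
    }
  } else {
    h0 <- floor(src_h); w0 <- floor(src_w)
    fh <- src_h - h0; fw <- src_w - w0
    corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    wts <- list((1 - fh) * (1 - fw), fh * (1 - fw), (1 - fh) * fw, fh * fw)
    idxs <- lapply(corners, function(cc) {
      hh <- h0 + cc[1]; ww <- w0 + cc[2]
      ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
      list(ok = ok, idx = ifelse(ok, hh + (ww - 1) * H, 1L))
    })
    apply_plane <- function(plane) {
      out <- numeric(H * W)
      for (q in 1:4) {
        contrib <- wts[[q]] * plane[idxs[[q]]$idx]
        contrib[!idxs[[q]]$ok] <- 0
        out <- out + contrib
      }
      out
    }
  }
  out <- vol
  extra <- prod(d[-(1:2)])
  m <- matrix(vol, nrow = H * W)
  om <- matrix(0, H * W, extra)
  for (j in seq_len(extra)) om[, j] <- apply_plane(m[, j])
  array(om, dim = d)
}

pad_to <- function(vol, target) {
  d <- dim(vol)
  if (all(d[1:3] >= target)) return(vol)
  nd <- pmax(d[1:3], target)
  out <- array(0, dim = c(nd, if (length(d) == 4L) d[4] else NULL))
  if (length(d) == 4L)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- vol
  else out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
  out
}

crop_at <- function(vol, start, target) {
  ix <- lapply(1:3, function(a) start[a] + seq_len(target[a]) - 1L)
  if (length(dim(vol)) == 4L) vol[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  else vol[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Training augmentation
#'
#' Deterministic given its seed: random axis flips (p = 0.5 each), a random
#' in-plane rotation (uniform in +-`max_rotation` degrees about the
#' through-plane axis; trilinear for images, nearest-neighbor for labels),
#' pad-then-random-crop to `target_shape`, and additive Gaussian noise
#' (z-scored units) on the images only. The same geometric transform is
#' applied to images and labels; labels never receive noise.
#'
#' @param case an `nl_case` (normally z-scored first).
#' @param seed integer seed; identical seeds give identical output.
#' @param target_shape output spatial shape.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param max_rotation rotation range in degrees.
#' @return the augmented case.
#' @export
augment <- function(case, seed, target_shape = c(192, 192, 128),
                    noise_sigma = 0.1, max_rotation = 15) {
  with_seed(seed, {
    seqs <- case$sequences
    labs <- case$labels
    for (ax in 1:3) if (runif(1) < 0.5) {
      ix <- rev(seq_len(dim(seqs)[ax]))
      seqs <- switch(ax, seqs[ix, , , , drop = FALSE],
                     seqs[, ix, , , drop = FALSE],
                     seqs[, , ix, , drop = FALSE])
      labs <- switch(ax, labs[ix, , , drop = FALSE],
                     labs[, ix, , drop = FALSE],
                     labs[, , ix, drop = FALSE])
    }
    ang <- runif(1, -max_rotation, max_rotation)
    seqs <- rotate_inplane(seqs, ang, nearest = FALSE)
    labs <- array(as.integer(rotate_inplane(labs, ang, nearest = TRUE)),
                  dim = dim(labs))
    seqs <- pad_to(seqs, target_shape)
    labs <- pad_to(labs, target_shape)
    room <- dim(labs)[1:3] - target_shape
    start <- vapply(room, function(r) if (r > 0) sample.int(r + 1L, 1) else 1L,
                    1L)
    seqs <- crop_at(seqs, start, target_shape)
    labs <- crop_at(labs, start, target_shape)
    seqs <- seqs + array(rnorm(length(seqs), sd = noise_sigma), dim = dim(seqs))
    case$sequences <- array(seqs, dim = c(target_shape, dim(seqs)[4]))
    case$labels <- array(as.integer(labs), dim = target_shape)
    case
  })
}

#' Deterministic 7:1:2 dataset split
#'
#' Shuffles the case ids with the given seed and assigns
#' `floor(0.7 n)` / `floor(0.1 n)` / remainder cases to train / validation /
#' test (for the default 7:1:2 ratios; general ratios use the same
#' floor/floor/remainder rule).
#'
#' @param case_ids character vector of at least 10 case ids.
#' @param ratios length-3 positive weights.
#' @param seed integer seed.
#' @return list of class `split_manifest` with `train`, `val`, `test`,
#'   `seed`, `ratios`.
#' @export
split_dataset <- function(case_ids, ratios = c(7, 1, 2), seed = 1) {
  n <- length(case_ids)
  if (n < 10) stop("need at least 10 cases, got ", n)
  fr <- ratios / sum(ratios)
  n_train <- floor(fr[1] * n)
  n_val <- floor(fr[2] * n)
  ids <- with_seed(seed, sample(case_ids))
  structure(list(train = ids[seq_len(n_train)],
                 val = ids[n_train + seq_len(n_val)],
                 test = ids[(n_train + n_val + 1):n],
                 seed = as.integer(seed), ratios = as.numeric(ratios)),
            class = "split_manifest")
}

#' Read/write a split manifest as JSON
#'
#' @param manifest a `split_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m[c("train", "val", "test", "seed", "ratios")],
            class = "split_manifest")
}
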