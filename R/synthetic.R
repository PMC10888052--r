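# Seed-reproducible multi-sequence phantom cases with nested tumor
# sub-regions. A brain ellipsoid sits on a zero background; each tumor is a
# triplet of nested ellipsoids assigning the label codes ET inside NCR-core
# inside an edema shell, so the derived sub-regions ET/TC/WT nest by
# construction. Image channels are the base tissue intensity plus per-region
# contrast offsets emulating the four standard MRI sequences (edema bright on
# the FLAIR-like channel, enhancing tumor bright on the T1ce-like channel),
# plus additive Gaussian noise inside the brain; labels stay noise-free and
# the background stays exactly 0 (as in skull-stripped data).

default_contrast <- function() {
  # rows: tissue regions; columns: sequences (t1, t1ce, t2, flair)
  m <- rbind(brain = c(0, 0, 0, 0),
             NCR = c(-0.3, -0.2, 0.3, 0.2),
             ED = c(0.1, 0.1, 0.6, 0.8),
             ET = c(0.2, 1.0, 0.2, 0.2))
  colnames(m) <- SEQUENCE_NAMES
  m
}

#' Phantom generator parameters
#'
#' Defaults are the desk-scale test conditions: 32 x 32 x 16 volumes, four
#' sequences, one tumor whose whole-tumor radius spans 45-60% of the smallest
#' half-extent, with region radius ratios ET : TC : WT = 0.45 : 0.7 : 1. The
#' resulting voxel-count ratio |ET| / |WT| stays well below 0.2, mimicking the
#' strong class imbalance of real tumor data and exercising the sub-region
#' weighting; base intensity 1 and noise sigma 0.1 in intensity units.
#'
#' @param shape spatial shape `(H, W, D)`.
#' @param num_sequences number of image channels.
#' @param brain_radius_frac brain ellipsoid semi-axes as a fraction of each
#'   half-extent.
#' @param tumor_count number of tumors.
#' @param wt_radius_frac range (min, max) of the whole-tumor radius as a
#'   fraction of the smallest half-extent.
#' @param region_radius_ratios radii of (ET, TC) relative to WT; must be
#'   increasing and below 1 so the regions nest.
#' @param contrast region-by-sequence intensity offset table.
#' @param base_intensity brain tissue intensity.
#' @param noise_sigma additive Gaussian noise level.
#' @param spacing voxel spacing.
#' @param seed integer seed.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(32, 32, 16), num_sequences = 4,
                           brain_radius_frac = 0.9, tumor_count = 1,
                           wt_radius_frac = c(0.45, 0.60),
                           region_radius_ratios = c(ET = 0.45, TC = 0.70),
                           contrast = default_contrast(),
                           base_intensity = 1, noise_sigma = 0.1,
                           spacing = c(1, 1, 1), seed = 1) {
  if (any(diff(c(region_radius_ratios, 1)) <= 0))
    stop("region radii must be increasing (ET < TC < WT)")
  if (num_sequences != ncol(contrast))
    stop("contrast table needs one column per sequence")
  structure(list(shape = as.integer(shape), num_sequences = num_sequences,
                 brain_radius_frac = brain_radius_frac,
                 tumor_count = tumor_count,
                 wt_radius_frac = wt_radius_frac,
                 region_radius_ratios = region_radius_ratios,
                 contrast = contrast, base_intensity = base_intensity,
                 noise_sigma = noise_sigma, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

ellipsoid_mask <- function(shape, center, radii) {
  gh <- (seq_len(shape[1]) - center[1]) / radii[1]
  gw <- (seq_len(shape[2]) - center[2]) / radii[2]
  gd <- (seq_len(shape[3]) - center[3]) / radii[3]
  outer(outer(gh^2, gw^2, "+"), gd^2, "+") <= 1
}

#' Generate one phantom case
#'
#' @param params a [phantom_params()].
#' @param case_id identifier for the generated case.
#' @return an `nl_case` (see [load_case()]); identical seeds give
#'   bit-identical cases.
#' @export
generate_phantom <- function(params, case_id = sprintf("phantom_%03d",
                                                       params$seed)) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    shp <- params$shape
    half <- shp / 2
    center <- (shp + 1) / 2
    brain_r <- params$brain_radius_frac * half
    brain <- ellipsoid_mask(shp, center, brain_r)
    labels <- array(0L, dim = shp)
    tumors <- vector("list", params$tumor_count)
    for (t in seq_len(params$tumor_count)) {
      placed <- FALSE
      for (try in seq_len(100)) {
        rwt <- runif(1, params$wt_radius_frac[1], params$wt_radius_frac[2]) *
          min(half)
        radii <- c(rwt, rwt, rwt) * runif(3, 0.85, 1.15)
        ctr <- center + (runif(3, -1, 1) * (brain_r - radii) * 0.7)
        # conservative fit check: WT bounding box inside the brain ellipsoid
        lo <- ctr - radii
        hi <- ctr + radii
        ok <- all(((lo - center) / brain_r)^2 <= 1) &&
          all(((hi - center) / brain_r)^2 <= 1)
        if (!ok) next
        wt <- ellipsoid_mask(shp, ctr, radii) & brain
        tc <- ellipsoid_mask(shp, ctr, radii * params$region_radius_ratios[["TC"]])
        et <- ellipsoid_mask(shp, ctr, radii * params$region_radius_ratios[["ET"]])
        if (!any(et)) next
        labels[wt] <- LABEL_CODES[["ED"]]
        labels[tc & wt] <- LABEL_CODES[["NCR"]]
        labels[et & wt] <- LABEL_CODES[["ET"]]
        tumors[[t]] <- list(center = ctr, radii = radii)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place tumor ", t, " inside the brain")
    }
    seqs <- array(0, dim = c(shp, params$num_sequences))
    tissue <- c("brain", "NCR", "ED", "ET")
    region_of <- c(brain = 0, NCR = 1, ED = 2, ET = 3)
    for (s in seq_len(params$num_sequences)) {
      v <- array(0, dim = shp)
      v[brain] <- params$base_intensity
      for (tn in tissue[-1]) {
        sel <- labels == region_of[[tn]]
        v[sel] <- params$base_intensity + params$contrast[tn, s]
      }
      v[brain] <- v[brain] + rnorm(sum(brain), sd = params$noise_sigma)
      seqs[, , , s] <- v
    }
    # separability guard: adjacent region means differ by >= 3 sigma on at
    # least one channel
    check_pairs <- list(c("brain", "ED"), c("ED", "NCR"), c("NCR", "ET"))
    for (pr in check_pairs) {
      sep <- max(abs(params$contrast[pr[1], ] - params$contrast[pr[2], ]))
      if (sep < 3 * params$noise_sigma)
        stop("contrast table does not separate ", pr[1], " from ", pr[2],
             " by 3 * noise_sigma on any channel")
    }
    structure(list(case_id = case_id, sequences = seqs, labels = labels,
                   spacing = params$spacing, paths = character(),
                   tumors = tumors),
              class = "nl_case")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom cases in the NIfTI case-directory layout and returns a
#' deterministic 7:1:2 split manifest over them.
#'
#' @param n number of cases (>= 10).
#' @param params a [phantom_params()] template; each case uses a sub-seed
#'   derived from `params$seed` and the case index.
#' @param out_dir output directory.
#' @param ratios split ratios.
#' @return a `split_manifest`; the manifest JSON is written alongside the
#'   cases.
#' @export
generate_dataset <- function(n, params = phantom_params(), out_dir,
                             ratios = c(7, 1, 2)) {
  if (n < 10) stop("need n >= 10 cases")
  ids <- character(n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    case <- generate_phantom(p, case_id = sprintf("phantom_%03d", i))
    write_case(case, out_dir,
               seq_names = SEQUENCE_NAMES[seq_len(params$num_sequences)])
    ids[i] <- case$case_id
  }
  manifest <- split_dataset(ids, ratios, seed = params$seed)
  write_manifest(manifest, file.path(out_dir, "split.json"))
  manifest
}

# in-memory convenience used by tests and the worked examples
generate_phantom_set <- function(n, params = phantom_params()) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    generate_phantom(p, case_id = sprintf("phantom_%03d", i))
  })
}
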