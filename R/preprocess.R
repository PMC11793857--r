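#' Normalize a Hounsfield-unit volume to \[0, 1\]
#'
#' Intensities are clipped to the CT working range \[-1024, 2500\] HU
#' (air to dense cortical bone), shifted to positive units and divided by
#' 3524, so -1024 maps to 0 and 2500 maps to 1.
#'
#' @param vol an [ct_volume()] with `units == "HU"`.
#' @return A normalized [ct_volume()].
#' @export
hu_normalize <- function(vol) {
  stopifnot(inherits(vol, "xcel_ct"))
  if (vol$units != "HU") stop("input volume is already normalized")
  if (!all(is.finite(vol$data))) stop("volume contains non-finite voxels")
  x <- pmin(pmax(vol$data, -1024), 2500)
  ct_volume((x + 1024) / 3524, vol$spacing_mm, units = "normalized")
}

#' Crop a CT/label pair to the bounding box of the labelled anatomy
#'
#' Removes all slices along every axis where neither bone label is present,
#' optionally padded by a margin, and records the offset for inverse mapping.
#'
#' @param vol an [ct_volume()].
#' @param labels the aligned [label_volume()].
#' @param margin extra voxels kept on each side of the bounding box.
#' @return list with the cropped `vol`, `labels`, and the 1-based `offset`
#'   of the crop origin in the source grid.
#' @export
crop_to_labels <- function(vol, labels, margin = 0L) {
  stopifnot(identical(dim(vol$data), dim(labels$data)))
  nz <- which(labels$data != 0L, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("label volume is empty; nothing to crop to")
  d <- dim(vol$data)
  lo <- pmax(apply(nz, 2, min) - margin, 1L)
  hi <- pmin(apply(nz, 2, max) + margin, d)
  list(vol = ct_volume(vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                drop = FALSE],
                       vol$spacing_mm, units = vol$units),
       labels = label_volume(labels$data[lo[1]:hi[1], lo[2]:hi[2],
                                         lo[3]:hi[3], drop = FALSE],
                             labels$spacing_mm),
       offset = as.integer(lo))
}

# Per-axis window offsets: the minimal number of equally spaced windows such
# that neighbouring windows overlap by at least `min_overlap_frac * edge`.
axis_offsets <- function(len, edge, min_overlap_frac) {
  if (len <= edge) return(1L)
  stride_max <- floor((1 - min_overlap_frac) * edge)
  n <- 1L + as.integer(ceiling((len - edge) / stride_max))
  unique(as.integer(round(seq(0, len - edge, length.out = n))) + 1L)
}

#' Decompose a volume into overlapping cubic patches
#'
#' Each axis is covered by the minimal number of equally spaced windows of
#' `patch_edge` voxels whose neighbours overlap by at least
#' `min_overlap_frac * patch_edge`; axes shorter than the patch edge are
#' symmetrically zero-padded first.
#'
#' @param vol 3D array (or `xcel_ct`, in which case its data is used).
#' @param patch_edge cubic patch edge in voxels.
#' @param min_overlap_frac minimum fractional overlap between neighbouring
#'   patches along each axis.
#' @return An object of class `xcel_patchset`: `patches` (list of
#'   sub-volume + 1-based `offset`), `patch_edge`, `source_shape` (after
#'   padding), and the symmetric `pad_lo` applied per axis.
#' @export
extract_patches <- function(vol, patch_edge = 160L, min_overlap_frac = 0.25) {
  x <- if (inherits(vol, "xcel_ct")) vol$data else vol
  if (patch_edge <= 0) stop("patch_edge must be positive")
  d <- dim(x)
  pad_lo <- pmax(0L, as.integer(floor((patch_edge - d) / 2)))
  pad_hi <- pmax(0L, as.integer(patch_edge - d - pad_lo))
  if (any(pad_lo + pad_hi > 0)) {
    d2 <- d + pad_lo + pad_hi
    xp <- array(0, d2)
    xp[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
       pad_lo[3] + seq_len(d[3])] <- x
    x <- xp
    d <- d2
  }
  offs <- lapply(seq_len(3), function(a)
    axis_offsets(d[a], patch_edge, min_overlap_frac))
  grid <- expand.grid(i = offs[[1]], j = offs[[2]], k = offs[[3]])
  patches <- lapply(seq_len(nrow(grid)), function(r) {
    o <- as.integer(unlist(grid[r, ]))
    list(data = x[o[1]:(o[1] + patch_edge - 1),
                  o[2]:(o[2] + patch_edge - 1),
                  o[3]:(o[3] + patch_edge - 1), drop = FALSE],
         offset = o)
  })
  structure(list(patches = patches, patch_edge = as.integer(patch_edge),
                 source_shape = d, pad_lo = pad_lo),
            class = "xcel_patchset")
}

#' Stitch per-class probability patches back into a full volume
#'
#' Overlapping voxels take the arithmetic mean of the contributing patch
#' probabilities; per-voxel class probabilities are then renormalized to
#' sum to one (unless `renormalize = FALSE`).
#'
#' @param patchset an `xcel_patchset` whose patches carry `data` arrays of
#'   shape (edge, edge, edge, n_classes).
#' @param renormalize renormalize class probabilities per voxel.
#' @return probability array of shape (source_shape, n_classes).
#' @export
stitch_patches <- function(patchset, renormalize = TRUE) {
  stopifnot(inherits(patchset, "xcel_patchset"))
  d <- patchset$source_shape
  e <- patchset$patch_edge
  nc <- dim(patchset$patches[[1]]$data)[4]
  if (is.na(nc)) nc <- 1L
  acc <- array(0, c(d, nc))
  cnt <- array(0, d)
  for (p in patchset$patches) {
    o <- p$offset
    if (any(o < 1) || any(o + e - 1 > d))
      stop("patch offset outside the source volume")
    ii <- o[1]:(o[1] + e - 1); jj <- o[2]:(o[2] + e - 1)
    kk <- o[3]:(o[3] + e - 1)
    pd <- p$data
    dim(pd) <- c(e, e, e, nc)
    acc[ii, jj, kk, ] <- acc[ii, jj, kk, , drop = FALSE] + pd
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
  }
  if (any(cnt == 0)) stop("stitching left uncovered voxels")
  acc <- acc / as.vector(cnt)
  if (renormalize && nc > 1) {
    s <- array(0, d)
    for (c in seq_len(nc)) s <- s + acc[, , , c]
    acc <- acc / pmax(as.vector(s), 1e-12)
  }
  acc
}

# Least-squares sphere fit: |p|^2 = 2 p . c + (R^2 - |c|^2).
fit_sphere <- function(pts) {
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  fit <- tryCatch(lm.fit(A, b), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients)) ||
      fit$rank < 4) return(NULL)
  ce <- fit$coefficients[1:3]
  r2 <- fit$coefficients[4] + sum(ce^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(centre = unname(ce), radius = sqrt(r2))
}

#' Extract a glenohumeral-joint-centred crop
#'
#' The humeral head centre is estimated by a least-squares sphere fit to the
#' boundary voxels of the superior third of the humerus label; the glenoid
#' point is the scapula voxel nearest that centre; the crop of
#' `crop_edge`^3 voxels is centred at the midpoint of the two, zero-padding
#' the CT outside the volume. A degenerate sphere fit falls back to the
#' humerus centroid with a warning.
#'
#' @param vol normalized [ct_volume()].
#' @param labels aligned [label_volume()] containing both bone classes.
#' @param crop_edge crop size in voxels (default 80, so that three 2x
#'   poolings give a 10^3 bottleneck).
#' @param truth optional [condition_labels()] attached to the crop.
#' @return An object of class `xcel_ghcrop`: `vol` (crop_edge^3 array),
#'   `labels` (crop of the label volume), `truth`, `centre` (1-based voxel
#'   coordinates of the crop centre in the source grid), `spacing_mm`.
#' @export
extract_gh_crop <- function(vol, labels, crop_edge = 80L, truth = NULL) {
  stopifnot(identical(dim(vol$data), dim(labels$data)))
  lab <- labels$data
  if (!any(lab == 1L)) stop("humerus label (1) missing")
  if (!any(lab == 2L)) stop("scapula label (2) missing")
  sp <- labels$spacing_mm
  hum <- which(lab == 1L, arr.ind = TRUE)
  zlo <- min(hum[, 3]); zhi <- max(hum[, 3])
  zcut <- zlo + 2 / 3 * (zhi - zlo)
  top <- hum[hum[, 3] >= zcut, , drop = FALSE]
  edges <- cpp_morph_edges(array(as.integer(lab == 1L), dim(lab)), 2L)
  bnd <- top[edges[top] == 1L, , drop = FALSE]
  if (nrow(bnd) < 10) bnd <- top
  pts <- sweep(bnd - 1, 2, sp, `*`)   # voxel i sits at (i - 1) * spacing mm
  fit <- fit_sphere(pts)
  if (is.null(fit)) {
    warning("degenerate sphere fit; falling back to the humerus centroid")
    centre_mm <- colMeans(sweep(hum - 1, 2, sp, `*`))
  } else centre_mm <- fit$centre
  scap <- which(lab == 2L, arr.ind = TRUE)
  spts <- sweep(scap - 1, 2, sp, `*`)
  d2 <- (spts[, 1] - centre_mm[1])^2 + (spts[, 2] - centre_mm[2])^2 +
    (spts[, 3] - centre_mm[3])^2
  glen_mm <- spts[which.min(d2), ]
  mid <- (centre_mm + glen_mm) / 2 / sp + 1      # voxel coordinates
  d <- dim(lab)
  lo <- as.integer(round(mid) - crop_edge %/% 2 + 1L)
  take <- function(src, fill) {
    out <- array(fill, rep(crop_edge, 3))
    src_lo <- pmax(lo, 1L); src_hi <- pmin(lo + crop_edge - 1L, d)
    if (any(src_lo > src_hi)) return(out)
    dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      src[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    out
  }
  structure(list(vol = take(vol$data, 0),
                 labels = array(as.integer(take(labels$data, 0L)),
                                rep(crop_edge, 3)),
                 truth = truth,
                 centre = mid, spacing_mm = sp),
            class = "xcel_ghcrop")
}

#' Mirror a GH crop in the sagittal plane
#'
#' Flips the medial-lateral axis (axis 1); condition labels are unchanged
#' (grades are side-independent).
#'
#' @param crop an `xcel_ghcrop`.
#' @return the flipped crop.
#' @export
sagittal_flip <- function(crop) {
  stopifnot(inherits(crop, "xcel_ghcrop"))
  n <- dim(crop$vol)[1]
  crop$vol <- crop$vol[n:1, , , drop = FALSE]
  if (!is.null(crop$labels))
    crop$labels <- crop$labels[n:1, , , drop = FALSE]
  crop
}
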