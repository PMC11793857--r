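#' Synthetic shoulder phantoms with known segmentation and condition truth
#'
#' The generator composes signed distance fields for a spherical humeral head
#' with a cylindrical shaft, optional spherical-cap osteophytes fused to the
#' infero-lateral head, and a scapular plate whose glenoid face is a concave
#' spherical cut conforming to the head at a prescribed joint gap. Voxel
#' labels are obtained by thresholding the fields; ground-truth surfaces are
#' extracted from the continuous fields themselves (sub-voxel interpolation),
#' so they do not depend on the label voxelisation. Condition truth follows
#' the size-based grading conventions: osteophyte grade 0/1/2 for maximum
#' protrusion < 3 / 3-7 / > 7 mm, joint-space grade 0/1/2 for a gap
#' >= 3 mm / 1-3 mm / below one voxel, and eccentric alignment for a
#' cranio-caudal head shift >= 2 mm.
#'
#' @param grid_shape integer vector of 3 voxel counts per axis
#'   (medial-lateral, antero-posterior, caudo-cranial).
#' @param spacing_mm isotropic voxel edge in mm.
#' @param head_radius_mm humeral-head sphere radius (mm).
#' @param osteophyte_height_mm maximum osteophyte protrusion normal to the
#'   unperturbed head sphere (mm, >= 0).
#' @param osteophyte_count number of osteophyte caps (>= 0).
#' @param joint_gap_mm glenoid-to-head surface clearance (mm, >= 0).
#' @param eccentric_shift_mm cranial displacement of the head centre (mm).
#' @param bone_hu,tissue_hu mean intensities of bone and soft tissue (HU).
#' @param noise_sd_hu standard deviation of additive Gaussian noise (HU).
#' @param seed integer seed; the same seed yields bit-identical phantoms.
#' @return An object of class `xcel_phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(96L, 96L, 96L), spacing_mm = 1,
                           head_radius_mm = 18, osteophyte_height_mm = 0,
                           osteophyte_count = 0L, joint_gap_mm = 3,
                           eccentric_shift_mm = 0, bone_hu = 1200,
                           tissue_hu = 40, noise_sd_hu = 25, seed = 1L) {
  p <- list(grid_shape = as.integer(rep(grid_shape, length.out = 3)),
            spacing_mm = spacing_mm, head_radius_mm = head_radius_mm,
            osteophyte_height_mm = osteophyte_height_mm,
            osteophyte_count = as.integer(osteophyte_count),
            joint_gap_mm = joint_gap_mm,
            eccentric_shift_mm = eccentric_shift_mm,
            bone_hu = bone_hu, tissue_hu = tissue_hu,
            noise_sd_hu = noise_sd_hu, seed = as.integer(seed))
  stopifnot(all(p$grid_shape > 0), p$spacing_mm > 0, p$head_radius_mm > 0,
            p$osteophyte_height_mm >= 0, p$osteophyte_count >= 0,
            p$joint_gap_mm >= 0, p$eccentric_shift_mm >= 0,
            p$noise_sd_hu >= 0)
  class(p) <- "xcel_phantom_params"
  p
}

# Condition grading applied to generating parameters.
grade_os <- function(height_mm) {
  if (height_mm < 3) 0L else if (height_mm <= 7) 1L else 2L
}
grade_js <- function(gap_mm, spacing_mm) {
  if (gap_mm < max(1, spacing_mm)) 2L else if (gap_mm < 3) 1L else 0L
}
grade_hsa <- function(shift_mm) {
  if (shift_mm >= 2) 1L else 0L
}

#' Clinical condition grades for one case
#'
#' @param os_grade osteophyte-size grade in 0..2.
#' @param js_grade joint-space grade in 0..2.
#' @param hsa humeroscapular alignment, 0 concentric / 1 eccentric.
#' @return An `xcel_condition_labels` list.
#' @export
condition_labels <- function(os_grade, js_grade, hsa) {
  stopifnot(os_grade %in% 0:2, js_grade %in% 0:2, hsa %in% 0:1)
  structure(list(os_grade = as.integer(os_grade),
                 js_grade = as.integer(js_grade), hsa = as.integer(hsa)),
            class = "xcel_condition_labels")
}

# Internal scene description shared by the SDF and the validity check.
phantom_scene <- function(p) {
  sp <- p$spacing_mm
  ext <- (p$grid_shape - 1) * sp
  r <- p$head_radius_mm
  s_o <- if (p$osteophyte_count > 0) p$osteophyte_height_mm else 0
  centre <- c(0.55 * ext[1], 0.5 * ext[2],
              0.5 * ext[3] + p$eccentric_shift_mm)
  shaft_r <- 0.45 * r
  plate_hi <- centre[1] - r - p$joint_gap_mm + 0.45 * r
  plate_lo <- plate_hi - (0.35 * r + min(6, r / 3))
  # Glenoid fossa: spherical cut with curvature radius larger than the head
  # (the glenoid is less conforming than the humeral head), so the
  # head-to-glenoid clearance has a unique minimum of joint_gap_mm at the
  # fossa pole. The cut follows the (possibly shifted) head centre, keeping
  # the clearance invariant under eccentric displacement.
  carve_r <- 1.6 * r
  carve_c <- centre + c(carve_r - r - p$joint_gap_mm, 0, 0)
  list(ext = ext, centre = centre, r = r, s_o = s_o, shaft_r = shaft_r,
       shaft_zbot = 2 * sp, plate_lo = plate_lo, plate_hi = plate_hi,
       plate_wy = 1.1 * r, plate_wz = 1.3 * r,
       carve_r = carve_r, carve_c = carve_c,
       centre0 = c(centre[1], centre[2], 0.5 * ext[3]))
}

check_geometry <- function(p) {
  sc <- phantom_scene(p)
  sp <- p$spacing_mm
  ok <- sc$centre[1] + sc$r + sc$s_o <= sc$ext[1] - sp &&
    sc$plate_lo >= sp &&
    sc$centre[3] + sc$r <= sc$ext[3] - sp &&
    sc$centre[2] + sc$plate_wy <= sc$ext[2] - sp &&
    sc$centre[2] - sc$plate_wy >= sp
  if (!ok)
    stop(errorCondition(
      "phantom geometry does not fit the voxel grid; enlarge grid_shape or shrink the anatomy",
      class = c("xcel_geometry_error", "error", "condition")))
  invisible(sc)
}

# Candidate infero-lateral osteophyte directions (unit vectors), chosen to
# keep cap apices well away from the shaft and the glenoid.
osteophyte_dirs <- function() {
  d <- rbind(c(0.80, 0.25, -0.45), c(0.80, -0.25, -0.45),
             c(0.95, 0.00, -0.30), c(0.65, 0.45, -0.55),
             c(0.65, -0.45, -0.55), c(0.85, 0.00, -0.52))
  d / sqrt(rowSums(d^2))
}

#' Generate one synthetic shoulder phantom
#'
#' @param params an [phantom_params()] object.
#' @return An object of class `xcel_phantom`: CT volume (`ct`), label volume
#'   (`labels`, 0 background / 1 humerus / 2 scapula), ground-truth surfaces
#'   (`humerus_morph_mesh` with osteophytes, `humerus_cleared_mesh` without,
#'   `scapula_mesh`), condition `truth`, and the generating `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "xcel_phantom_params"))
  sc <- check_geometry(params)
  p <- params
  sp <- p$spacing_mm
  d <- p$grid_shape
  xs <- (seq_len(d[1]) - 1) * sp
  ys <- (seq_len(d[2]) - 1) * sp
  zs <- (seq_len(d[3]) - 1) * sp
  X <- array(xs, d)
  Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  ce <- sc$centre
  dist_head <- sqrt((X - ce[1])^2 + (Y - ce[2])^2 + (Z - ce[3])^2)
  sdf_sphere <- dist_head - sc$r
  rad_shaft <- sqrt((X - ce[1])^2 + (Y - ce[2])^2) - sc$shaft_r
  sdf_shaft <- pmax(rad_shaft, pmax(Z - ce[3], sc$shaft_zbot - Z))
  sdf_cleared <- pmin(sdf_sphere, sdf_shaft)
  sdf_morph <- sdf_cleared
  if (p$osteophyte_count > 0 && p$osteophyte_height_mm > 0) {
    dirs <- osteophyte_dirs()
    s_o <- p$osteophyte_height_mm
    r_b <- 0.75 * s_o + 0.5
    for (k in seq_len(p$osteophyte_count)) {
      u <- dirs[((k - 1) %% nrow(dirs)) + 1, ]
      cb <- ce + u * (sc$r + s_o - r_b)
      sdf_b <- sqrt((X - cb[1])^2 + (Y - cb[2])^2 + (Z - cb[3])^2) - r_b
      sdf_morph <- pmin(sdf_morph, sdf_b)
    }
  }
  slab <- pmax(sc$plate_lo - X, X - sc$plate_hi)
  slab <- pmax(slab, abs(Y - ce[2]) - sc$plate_wy)
  slab <- pmax(slab, abs(Z - sc$centre0[3]) - sc$plate_wz)
  dist_carve <- sqrt((X - sc$carve_c[1])^2 + (Y - sc$carve_c[2])^2 +
                       (Z - sc$carve_c[3])^2)
  sdf_scap <- pmax(slab, sc$carve_r - dist_carve)

  labels <- array(0L, d)
  labels[sdf_morph < 0] <- 1L
  labels[sdf_scap < 0 & labels == 0L] <- 2L

  frac <- stats::plogis(-pmin(sdf_morph, sdf_scap) / (0.5 * sp))
  ct <- p$tissue_hu + (p$bone_hu - p$tissue_hu) * frac
  if (p$noise_sd_hu > 0)
    ct <- ct + with_seed(p$seed, array(rnorm(prod(d), sd = p$noise_sd_hu), d))

  mesh_of <- function(sdf) {
    m <- cpp_march_tets(sdf, 0, rep(sp, 3), TRUE)
    surface_mesh(m$vertices, m$faces)
  }
  truth <- condition_labels(grade_os(sc$s_o),
                            grade_js(p$joint_gap_mm, sp),
                            grade_hsa(p$eccentric_shift_mm))
  structure(list(
    ct = ct_volume(ct, sp, units = "HU"),
    labels = label_volume(labels, sp),
    humerus_morph_mesh = mesh_of(sdf_morph),
    humerus_cleared_mesh = mesh_of(sdf_cleared),
    scapula_mesh = mesh_of(sdf_scap),
    truth = truth, params = p), class = "xcel_phantom")
}

#' Generate a phantom dataset stratified over condition grades
#'
#' Osteophyte grades are allocated by largest-remainder quotas of `class_mix`
#' (so a uniform mix with `n` divisible by 3 is exactly stratified); joint
#' space and alignment grades are sampled from the study prevalences
#' (JS 38.2/27.2/34.6%, HSA 56.1/43.9%). Parameter ranges per grade keep
#' osteophyte heights at least one voxel away from the 3/7 mm boundaries.
#'
#' @param n number of phantoms (>= 1).
#' @param class_mix sampling weights over the three osteophyte grades;
#'   defaults to the study prevalences 31.1/36.1/32.8%.
#' @param params template [phantom_params()] giving grid, spacing and
#'   intensity settings.
#' @param seed root seed; phantom seeds are derived from it.
#' @return list of `xcel_phantom` objects.
#' @export
generate_dataset <- function(n, class_mix = c(0.311, 0.361, 0.328),
                             params = phantom_params(), seed = 1L) {
  stopifnot(n >= 1)
  if (length(class_mix) != 3 || any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix must be three non-negative weights with positive sum")
  w <- class_mix / sum(class_mix)
  quota <- floor(n * w)
  rem <- n - sum(quota)
  if (rem > 0) {
    frac <- n * w - quota
    quota[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      quota[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  os_grades <- rep(0:2, times = quota)
  with_seed(seed, {
    os_grades <- sample(os_grades)
    js_grades <- sample(0:2, n, replace = TRUE, prob = c(0.382, 0.272, 0.346))
    hsa <- sample(0:1, n, replace = TRUE, prob = c(0.561, 0.439))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    height <- vapply(os_grades, function(g)
      switch(g + 1L, runif(1, 0.8, 2.0), runif(1, 4, 6), runif(1, 8, 11)),
      numeric(1))
    count <- ifelse(os_grades == 0, sample(0:1, n, replace = TRUE),
                    sample(1:3, n, replace = TRUE))
    gap <- vapply(js_grades, function(g)
      switch(g + 1L, runif(1, 3.5, 5), runif(1, 1.5, 2.8), runif(1, 0, 0.6)),
      numeric(1))
    shift <- ifelse(hsa == 1, runif(n, 2.5, 5), runif(n, 0, 0.8))
  })
  lapply(seq_len(n), function(i) {
    p <- params
    p$osteophyte_height_mm <- if (count[i] > 0) height[i] else 0
    p$osteophyte_count <- as.integer(max(count[i],
                                         if (os_grades[i] > 0) 1L else 0L))
    p$joint_gap_mm <- gap[i]
    p$eccentric_shift_mm <- shift[i]
    p$seed <- seeds[i]
    generate_phantom(p)
  })
}

#' Write a phantom to disk (NIfTI volumes, PLY meshes, truth CSV row)
#'
#' @param phantom an `xcel_phantom`.
#' @param dir output directory (created if missing).
#' @param id file-name stem.
#' @return invisibly, the written file paths.
#' @export
write_phantom <- function(phantom, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctf <- file.path(dir, paste0(id, "_ct.nii.gz"))
  lbf <- file.path(dir, paste0(id, "_labels.nii.gz"))
  write_nifti_volume(phantom$ct$data, phantom$ct$spacing_mm, ctf)
  write_nifti_volume(phantom$labels$data, phantom$labels$spacing_mm, lbf)
  mf <- c(morph = file.path(dir, paste0(id, "_humerus_morph.ply")),
          cleared = file.path(dir, paste0(id, "_humerus_cleared.ply")),
          scapula = file.path(dir, paste0(id, "_scapula.ply")))
  write_ply(phantom$humerus_morph_mesh, mf["morph"])
  write_ply(phantom$humerus_cleared_mesh, mf["cleared"])
  write_ply(phantom$scapula_mesh, mf["scapula"])
  tf <- file.path(dir, paste0(id, "_truth.csv"))
  write.csv(data.frame(id = id, os = phantom$truth$os_grade,
                       js = phantom$truth$js_grade, hsa = phantom$truth$hsa),
            tf, row.names = FALSE)
  invisible(c(ct = ctf, labels = lbf, mf, truth = tf))
}
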