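#' CT volume container
#'
#' A 3D scalar grid with isotropic voxel spacing in mm. Axis convention:
#' dim 1 medial-lateral, dim 2 antero-posterior, dim 3 caudo-cranial
#' (1-based indices). `units` is either `"HU"` (raw Hounsfield) or
#' `"normalized"` (values in \[0, 1\]).
#'
#' @param data 3D numeric array.
#' @param spacing_mm voxel edge length(s) in mm (scalar or length 3).
#' @param units `"HU"` or `"normalized"`.
#' @export
ct_volume <- function(data, spacing_mm, units = c("HU", "normalized")) {
  units <- match.arg(units)
  stopifnot(length(dim(data)) == 3, all(spacing_mm > 0))
  if (units == "normalized" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("normalized CT volume must lie in [0, 1]")
  structure(list(data = data,
                 spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
                 units = units),
            class = "xcel_ct")
}

#' Label volume container
#'
#' Integer grid over {0 background, 1 proximal humerus, 2 scapula}, aligned
#' voxel-for-voxel with its CT volume.
#'
#' @param data 3D integer array with values in 0..2.
#' @param spacing_mm voxel edge length(s) in mm.
#' @export
label_volume <- function(data, spacing_mm) {
  stopifnot(length(dim(data)) == 3, all(spacing_mm > 0))
  if (!all(data %in% 0:2)) stop("labels must be integers in {0, 1, 2}")
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing_mm = rep(as.numeric(spacing_mm), length.out = 3)),
            class = "xcel_labels")
}

#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(vertices) < 4) stop("a surface mesh needs at least 4 vertices")
  if (!all(is.finite(vertices))) stop("mesh vertices must be finite")
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("faces reference vertices outside the mesh")
  structure(list(vertices = vertices, faces = faces), class = "xcel_mesh")
}

#' @export
print.xcel_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
print.xcel_phantom <- function(x, ...) {
  cat(sprintf(
    "shoulder phantom %s voxels @ %.2g mm | OS %d, JS %d, HSA %d\n",
    paste(dim(x$ct$data), collapse = "x"), x$ct$spacing_mm[1],
    x$truth$os_grade, x$truth$js_grade, x$truth$hsa))
  invisible(x)
}

#' Write / read a volume as NIfTI with spacing encoded in the header
#'
#' @param data 3D array.
#' @param spacing_mm voxel size in mm (scalar or length 3).
#' @param file output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_volume <- function(data, spacing_mm, file) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(spacing_mm, length.out = 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(file) {
  img <- RNifti::readNifti(file)
  list(data = array(as.numeric(img), dim(img)),
       spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write a mesh as ASCII PLY
#' @param mesh an `xcel_mesh`.
#' @param file output path.
#' @export
write_ply <- function(mesh, file) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]), con)
  if (nrow(f) > 0)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  invisible(file)
}

#' @rdname write_ply
#' @export
read_ply <- function(file) {
  lines <- readLines(file)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[(end + 1):(end + nv)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
  f <- matrix(0L, 0, 3)
  if (nf > 0) {
    fl <- lines[(end + nv + 1):(end + nv + nf)]
    fm <- matrix(as.integer(unlist(strsplit(fl, " "))), ncol = 4, byrow = TRUE)
    f <- fm[, 2:4, drop = FALSE] + 1L
  }
  surface_mesh(v, f)
}

#' Write a mesh as ASCII STL
#' @param mesh an `xcel_mesh`.
#' @param file output path.
#' @param name solid name written to the header.
#' @export
write_stl <- function(mesh, file, name = "surface") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
             (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
           (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
             (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
           (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
             (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.6g %.6g %.6g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.6g %.6g %.6g",
                         p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(file)
}
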