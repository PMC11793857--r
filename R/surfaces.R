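#' Extract the bone surface of one label class as a triangle mesh
#'
#' Isosurface of the binary class mask at level 0.5 by marching tetrahedra
#' (Kuhn 6-tetrahedron cube decomposition, sub-voxel edge interpolation);
#' only the largest connected surface component is kept and vertices are
#' scaled to mm by the voxel spacing.
#'
#' @param labels [label_volume()] or integer array.
#' @param class_id label value to extract (1 humerus, 2 scapula).
#' @param spacing_mm voxel size; taken from the label volume if omitted.
#' @return a [surface_mesh()].
#' @export
labels_to_mesh <- function(labels, class_id, spacing_mm = NULL) {
  if (inherits(labels, "xcel_labels")) {
    if (is.null(spacing_mm)) spacing_mm <- labels$spacing_mm
    labels <- labels$data
  }
  if (is.null(spacing_mm)) spacing_mm <- 1
  mask <- array(as.numeric(labels == class_id), dim(labels))
  if (!any(mask > 0)) stop(sprintf("class %s absent from labels", class_id))
  m <- cpp_march_tets(mask, 0.5, rep(spacing_mm, length.out = 3), TRUE)
  surface_mesh(m$vertices, m$faces)
}

#' One-way vertex distances between two meshes
#'
#' For every vertex of the target mesh, the Euclidean distance to the
#' nearest vertex of the predicted mesh; summarized by the RMSE, the mean
#' and the one-way Hausdorff distance (maximum).
#'
#' @param target reference [surface_mesh()].
#' @param predicted compared [surface_mesh()].
#' @return An `xcel_distance_report`: `distances` (per target vertex, mm),
#'   `rmse`, `mean`, `hausdorff`.
#' @export
one_way_distances <- function(target, predicted) {
  stopifnot(inherits(target, "xcel_mesh"), inherits(predicted, "xcel_mesh"))
  if (nrow(target$vertices) == 0 || nrow(predicted$vertices) == 0)
    stop("empty mesh")
  d <- cpp_nn_dist(target$vertices, predicted$vertices)
  structure(list(distances = d, rmse = sqrt(mean(d^2)), mean = mean(d),
                 hausdorff = max(d)),
            class = "xcel_distance_report")
}

#' @export
print.xcel_distance_report <- function(x, ...) {
  cat(sprintf("one-way distances: rmse %.3f mm | mean %.3f mm | hausdorff %.3f mm (n=%d)\n",
              x$rmse, x$mean, x$hausdorff, length(x$distances)))
  invisible(x)
}

#' Voxel overlap metrics per class
#'
#' Dice `2TP / (2TP + FP + FN)`, precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)` for each foreground class; a class absent from both
#' volumes is reported as `NA`.
#'
#' @param pred_labels predicted [label_volume()] or integer array.
#' @param target_labels reference labels of the same shape.
#' @param classes class values to evaluate.
#' @return data.frame with one row per class.
#' @export
overlap_metrics <- function(pred_labels, target_labels, classes = 1:2) {
  p <- if (inherits(pred_labels, "xcel_labels")) pred_labels$data
       else pred_labels
  t <- if (inherits(target_labels, "xcel_labels")) target_labels$data
       else target_labels
  if (!identical(dim(p), dim(t))) stop("label shapes differ")
  rows <- lapply(classes, function(k) {
    pp <- p == k; tt <- t == k
    tp <- sum(pp & tt); fp <- sum(pp & !tt); fn <- sum(!pp & tt)
    if (tp + fp + fn == 0)
      return(data.frame(class = k, dice = NA_real_, precision = NA_real_,
                        recall = NA_real_))
    data.frame(class = k,
               dice = 2 * tp / (2 * tp + fp + fn),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Automatic osteophyte-size grading from paired humerus surfaces
#'
#' The maximum protrusion `s_o` is the largest one-way distance from the
#' morphologic (osteophyte-bearing) surface to the osteophyte-cleared
#' surface; grades follow the size classes 0 (< 3 mm), 1 (3-7 mm, boundaries
#' inclusive) and 2 (> 7 mm).
#'
#' @param morph morphologic humerus [surface_mesh()].
#' @param cleared osteophyte-cleared humerus [surface_mesh()].
#' @return list with `s_o_mm` and integer `grade`.
#' @export
os_autolabel <- function(morph, cleared) {
  rep_ <- one_way_distances(morph, cleared)
  s_o <- rep_$hausdorff
  grade <- if (s_o < 3) 0L else if (s_o <= 7) 1L else 2L
  list(s_o_mm = s_o, grade = grade)
}
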