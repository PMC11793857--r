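#' Class score as a function of the bottleneck activations
#'
#' Recomputes the selected head's score from a given bottleneck activation
#' array through global average pooling and the dense classification branch.
#' For the softmax heads the score is the pre-softmax logit of the class; for
#' the sigmoid alignment head it is the logit (class 1) or its negative
#' (class 0). Used both by the activation-map computation and as the target
#' function for finite-difference gradient checks.
#'
#' @param model an `xcel_model`.
#' @param A bottleneck activation array (spatial dims x channels).
#' @param class_set one of "os", "js", "hsa".
#' @param class_index 0-based class within the set.
#' @return scalar score.
#' @export
score_from_bottleneck <- function(model, A,
                                  class_set = c("os", "js", "hsa"),
                                  class_index = 0L) {
  class_set <- match.arg(class_set)
  n_cls <- model$cfg$heads[[class_set]]
  max_idx <- if (class_set == "hsa") 1L else n_cls - 1L
  if (class_index < 0 || class_index > max_idx)
    stop(sprintf("class_index %d out of range for %s", class_index, class_set))
  p <- model$params$classification
  nz <- prod(dim(A)[1:3])
  pooled <- colSums(matrix(A, nz, dim(A)[4])) / nz
  d1 <- relu(drop(crossprod(p$dense1$W, pooled)) + p$dense1$b)
  d2 <- relu(drop(crossprod(p$dense2$W, d1)) + p$dense2$b)
  logit <- drop(crossprod(p[[class_set]]$W, d2)) + p[[class_set]]$b
  if (class_set == "hsa") {
    if (class_index == 1L) logit else -logit
  } else logit[class_index + 1]
}

# Analytic gradient of the selected score with respect to every bottleneck
# voxel; constant per feature map because pooling averages over positions.
bottleneck_score_grads <- function(model, A, class_set, class_index) {
  p <- model$params$classification
  nz <- prod(dim(A)[1:3])
  nf <- dim(A)[4]
  pooled <- colSums(matrix(A, nz, nf)) / nz
  d1 <- relu(drop(crossprod(p$dense1$W, pooled)) + p$dense1$b)
  d2 <- relu(drop(crossprod(p$dense2$W, d1)) + p$dense2$b)
  gl <- switch(class_set,
    os = replace(numeric(3), class_index + 1, 1),
    js = replace(numeric(3), class_index + 1, 1),
    hsa = if (class_index == 1L) 1 else -1)
  gd2 <- relu_bwd(drop(p[[class_set]]$W %*% gl), d2)
  gd1 <- relu_bwd(drop(p$dense2$W %*% gd2), d1)
  gpool <- drop(p$dense1$W %*% gd1)
  list(gpool = gpool, delta_per_voxel = gpool / nz, Z = as.integer(nz))
}

#' 3D gradient-weighted class activation map
#'
#' Runs the forward pass on the crop, selects the score of class
#' `class_index` in class set `class_set`, computes the gradients of the
#' score with respect to the bottleneck feature maps, averages them over the
#' spatial positions (Z = number of bottleneck voxels, 1000 for an 80^3
#' input) to obtain per-map weights, forms the ReLU of the weighted sum of
#' the feature maps, and upsamples the result trilinearly to the crop shape.
#'
#' @param model trained `xcel_model`.
#' @param crop normalized 3D array (a GH crop) or `xcel_ghcrop`.
#' @param class_set "os", "js" or "hsa".
#' @param class_index 0-based class within the set.
#' @return An `xcel_activation_map`: `heatmap` (crop-shaped, non-negative),
#'   `raw` (bottleneck-resolution map), `alpha` (per-map weights), `Z`,
#'   `class_set`, `class_index`.
#' @export
compute_gradcam <- function(model, crop, class_set = c("os", "js", "hsa"),
                            class_index = 0L) {
  class_set <- match.arg(class_set)
  x <- if (inherits(crop, "xcel_ghcrop")) crop$vol else crop
  fw <- nn_forward(model, x, seg = FALSE, cls = TRUE, keep = TRUE)
  A <- fw$cache$bott$A
  # validates the class index too
  score_from_bottleneck(model, A, class_set, class_index)
  gr <- bottleneck_score_grads(model, A, class_set, class_index)
  nf <- dim(A)[4]
  alpha_f <- gr$gpool / gr$Z          # spatial mean of the per-voxel gradients
  raw <- array(0, dim(A)[1:3])
  for (f in seq_len(nf)) raw <- raw + alpha_f[f] * A[, , , f]
  raw <- relu(raw)
  heat <- resize_trilinear(raw, dim(x))
  heat <- relu(heat)
  structure(list(heatmap = heat, raw = raw, alpha = alpha_f, Z = gr$Z,
                 class_set = class_set, class_index = as.integer(class_index)),
            class = "xcel_activation_map")
}

# Simple black-red-yellow heat colormap on values in [0, 1].
heat_rgb <- function(v) {
  r <- pmin(1, 2 * v)
  g <- pmin(1, pmax(0, 2 * v - 1))
  b <- numeric(length(v))
  cbind(r, g, b)
}

#' Overlay an activation map on its CT crop
#'
#' Min-max scales the heatmap to \[0, 1\] (a constant non-zero map scales to
#' 1), alpha-blends a heat colormap over the grayscale CT, and assembles a
#' montage of the mid axial, coronal and sagittal slices.
#'
#' @param map an `xcel_activation_map`.
#' @param crop the matching normalized crop (array or `xcel_ghcrop`).
#' @param opacity maximum blend weight of the heat layer.
#' @param file optional PNG path.
#' @return list with `rgb` (montage H x W x 3), `heat` (scaled map), and
#'   per-plane `panels`.
#' @export
overlay <- function(map, crop, opacity = 0.5, file = NULL) {
  x <- if (inherits(crop, "xcel_ghcrop")) crop$vol else crop
  h <- map$heatmap
  if (!identical(dim(h), dim(x))) stop("map and crop shapes differ")
  rng <- range(h)
  hn <- if (diff(rng) > 0) (h - rng[1]) / diff(rng)
        else array(as.numeric(rng[2] > 0), dim(h))
  xr <- range(x)
  gn <- if (diff(xr) > 0) (x - xr[1]) / diff(xr) else array(0, dim(x))
  d <- dim(x)
  mid <- (d + 1) %/% 2
  panel <- function(g2, h2) {
    a <- opacity * as.vector(h2)
    col <- heat_rgb(as.vector(h2))
    g <- as.vector(g2)
    array(c((1 - a) * g + a * col[, 1],
            (1 - a) * g + a * col[, 2],
            (1 - a) * g + a * col[, 3]), c(dim(g2), 3))
  }
  panels <- list(
    axial = panel(gn[, , mid[3]], hn[, , mid[3]]),
    coronal = panel(gn[, mid[2], ], hn[, mid[2], ]),
    sagittal = panel(gn[mid[1], , ], hn[mid[1], , ]))
  wtot <- sum(vapply(panels, function(p) dim(p)[2], 1))
  hmax <- max(vapply(panels, function(p) dim(p)[1], 1))
  rgb <- array(0, c(hmax, wtot, 3))
  at <- 0
  for (p in panels) {
    rgb[seq_len(dim(p)[1]), at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  if (!is.null(file)) png::writePNG(rgb, file)
  invisible(list(rgb = rgb, heat = hn, panels = panels))
}

#' Fraction of top-decile activation mass inside a region
#'
#' Thresholds the map at its 90th percentile and reports the share of the
#' retained activation mass lying inside the (optionally dilated) region
#' mask. Quantifies how well an activation map localizes to an anatomical
#' region of interest.
#'
#' @param map an `xcel_activation_map` or a non-negative array.
#' @param region_mask logical/0-1 array of the same shape.
#' @param top_frac mass-selection fraction (0.10 keeps the top decile).
#' @param dilate_vox dilate the region by this many voxels first.
#' @return scalar in \[0, 1\].
#' @export
localization_score <- function(map, region_mask, top_frac = 0.10,
                               dilate_vox = 0) {
  h <- if (inherits(map, "xcel_activation_map")) map$heatmap else map
  if (!identical(dim(h), dim(region_mask))) stop("shape mismatch")
  if (!any(region_mask > 0)) stop("empty region mask")
  if (max(h) <= 0) stop("activation map is identically zero")
  mask <- region_mask > 0
  if (dilate_vox > 0)
    mask <- cpp_edt3d(mask, c(1, 1, 1)) <= dilate_vox + 1e-9
  thr <- quantile(h, 1 - top_frac)
  sel <- h >= thr
  sum(h[sel & mask]) / sum(h[sel])
}
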