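#' Soft Dice score over foreground classes
#'
#' Mean over the foreground classes of `2 sum(p q) / (sum p + sum q + eps)`.
#'
#' @param pred_probs array (D, H, W, K) of per-class probabilities.
#' @param target_onehot array of the same shape, one-hot.
#' @param eps numerical stabilizer.
#' @param fg_only drop class 1 (background) from the mean.
#' @return scalar Dice score in \[0, 1\].
#' @export
dice_score <- function(pred_probs, target_onehot, eps = 1e-6,
                       fg_only = TRUE) {
  if (!identical(dim(pred_probs), dim(target_onehot)))
    stop("prediction and target shapes differ")
  cls <- dice_classes(target_onehot, fg_only)
  mean(vapply(cls, function(c) {
    p <- pred_probs[, , , c]; q <- target_onehot[, , , c]
    2 * sum(p * q) / (sum(p) + sum(q) + eps)
  }, 1))
}

# Foreground classes present in the target (classes no observer labelled do
# not enter the mean, so a perfect prediction scores exactly 1).
dice_classes <- function(target_onehot, fg_only) {
  K <- dim(target_onehot)[4]
  n <- prod(dim(target_onehot)[1:3])
  present <- which(colSums(matrix(target_onehot, n, K)) > 0)
  cls <- if (fg_only && K > 1) setdiff(present, 1L) else present
  if (!length(cls)) cls <- present
  cls
}

dice_grad <- function(pred_probs, target_onehot, eps = 1e-6,
                      fg_only = TRUE) {
  cls <- dice_classes(target_onehot, fg_only)
  g <- array(0, dim(pred_probs))
  for (c in cls) {
    p <- pred_probs[, , , c]; q <- target_onehot[, , , c]
    num <- 2 * sum(p * q); den <- sum(p) + sum(q) + eps
    g[, , , c] <- (2 * q / den - num / den^2) / length(cls)
  }
  g
}

#' Dice-weight schedule for the region loss
#'
#' Starts at 1, decreases linearly by 0.005 per iteration, and stays at 0.5
#' from iteration 100 onward, letting the Dice term dominate early training
#' before the distance-weighted cross-entropy gains influence.
#'
#' @param t iteration (epoch) index, >= 0.
#' @return alpha in \[0.5, 1\].
#' @export
alpha_schedule <- function(t) {
  if (any(t < 0) || any(t != floor(t))) stop("t must be a non-negative integer")
  pmax(0.5, 1 - 0.005 * t)
}

#' Distance-based voxel weight maps
#'
#' `d(x)` is the Euclidean distance (mm) to the nearest inter-class boundary
#' voxel. The near map `1 + gamma * exp(-d / tau)` emphasizes a boundary band
#' of width ~`tau`; the far map `1 + gamma * (1 - exp(-d / tau))` emphasizes
#' interior and background. A single-class volume has no boundary and yields
#' uniform maps with a warning.
#'
#' @param labels integer label array.
#' @param spacing_mm voxel size (scalar or length 3).
#' @param gamma peak excess weight.
#' @param tau decay length in mm.
#' @return list with `w_near`, `w_far`, and the distance map `d_mm`.
#' @export
distance_weight_maps <- function(labels, spacing_mm = 1, gamma = 5, tau = 3) {
  lab <- if (inherits(labels, "xcel_labels")) labels$data else labels
  sp <- rep(spacing_mm, length.out = 3)
  edges <- cpp_morph_edges(array(as.integer(lab), dim(lab)),
                           max(lab) + 1L)
  if (!any(edges > 0)) {
    warning("single-class label volume: uniform weight maps")
    ones <- array(1, dim(lab))
    return(list(w_near = ones, w_far = ones, d_mm = array(0, dim(lab))))
  }
  d <- cpp_edt3d(edges > 0L, sp)
  e <- exp(-d / tau)
  list(w_near = 1 + gamma * e, w_far = 1 + gamma * (1 - e), d_mm = d)
}

#' Boundary targets for the contour decoder
#'
#' Per-class boundaries from the morphological gradient with a 3^3
#' structuring element; overlaps resolve to the lower class index; non-edge
#' voxels are class 0.
#'
#' @param labels integer label array (or `xcel_labels`).
#' @return integer array of edge classes.
#' @export
edge_targets <- function(labels) {
  lab <- if (inherits(labels, "xcel_labels")) labels$data else labels
  cpp_morph_edges(array(as.integer(lab), dim(lab)), max(lab) + 1L)
}

#' Fraction of boundary voxels (the contour-loss weight beta)
#'
#' @param labels integer label array or list of arrays (a batch).
#' @return ratio of shape-boundary voxels to total voxels.
#' @export
boundary_fraction <- function(labels) {
  if (!is.list(labels)) labels <- list(labels)
  tot <- 0; bnd <- 0
  for (lab in labels) {
    e <- edge_targets(lab)
    tot <- tot + length(e)
    bnd <- bnd + sum(e > 0)
  }
  bnd / tot
}

# Weighted mean cross-entropy score C = exp(-sum(w * CE) / sum(w)) and its
# gradient with respect to the logits: dC/dz = -C * (w / sum w) * (p - y).
weighted_ce_score <- function(probs, onehot, w, clamp = 1e-12) {
  pt <- rowSums(matrix(probs, length(w), dim(probs)[4]) *
                  matrix(onehot, length(w), dim(onehot)[4]))
  ce <- -log(pmax(pt, clamp))
  wn <- as.vector(w) / sum(w)
  Cs <- exp(-sum(wn * ce))
  list(C = Cs, wn = wn)
}

#' Region loss of the mask decoder
#'
#' `L_r = 1 - (alpha * D + (1 - alpha) * C)` where `D` is the soft Dice score
#' and `C = exp(-weighted mean cross-entropy)` with near-boundary weights, so
#' both terms are scores in (0, 1\] and the loss vanishes at a perfect
#' one-hot prediction.
#'
#' @param pred_probs softmax output of the mask decoder (D, H, W, K).
#' @param target_onehot one-hot target of the same shape.
#' @param alpha Dice weight in \[0, 1\] (see [alpha_schedule()]).
#' @param w_near near-boundary weight map (defaults to uniform).
#' @param logits optional logits matching `pred_probs`; when supplied the
#'   returned `grad_logits` can be fed to the optimizer.
#' @return list with `loss`, `dice`, `C`, and (if `logits` given)
#'   `grad_logits`.
#' @export
region_loss <- function(pred_probs, target_onehot, alpha,
                        w_near = NULL, logits = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (min(pred_probs) < -1e-6 || max(pred_probs) > 1 + 1e-6)
    stop("pred_probs must be probabilities")
  if (is.null(w_near)) w_near <- array(1, dim(pred_probs)[1:3])
  D <- dice_score(pred_probs, target_onehot)
  ce <- weighted_ce_score(pred_probs, target_onehot, w_near)
  loss <- 1 - (alpha * D + (1 - alpha) * ce$C)
  out <- list(loss = loss, dice = D, C = ce$C)
  if (!is.null(logits)) {
    gD <- dice_grad(pred_probs, target_onehot)
    # softmax Jacobian for the Dice part
    n <- prod(dim(pred_probs)[1:3])
    P <- matrix(pred_probs, n, dim(pred_probs)[4])
    G <- matrix(gD, n, dim(pred_probs)[4])
    gz_dice <- P * (G - rowSums(G * P))
    gz_ce <- -ce$C * ce$wn *
      (P - matrix(target_onehot, n, dim(target_onehot)[4]))
    gz <- array(-alpha * gz_dice - (1 - alpha) * gz_ce, dim(pred_probs))
    out$grad_logits <- gz
  }
  out
}

#' Contour loss of the contour decoder
#'
#' `L_c = 1 - (beta * C + (1 - beta) * C_hat)` where `C` uses near-boundary
#' weights and the reverse term `C_hat` uses far-from-boundary weights, both
#' computed on the contour-decoder output against edge targets.
#'
#' @param pred_probs softmax output of the contour decoder.
#' @param target_onehot one-hot edge targets.
#' @param beta boundary fraction in \[0, 1\] (see [boundary_fraction()]).
#' @param w_near,w_far weight maps from [distance_weight_maps()].
#' @param logits optional logits for gradient computation.
#' @return list with `loss`, `C`, `C_rev`, and optionally `grad_logits`.
#' @export
contour_loss <- function(pred_probs, target_onehot, beta,
                         w_near = NULL, w_far = NULL, logits = NULL) {
  stopifnot(beta >= 0, beta <= 1)
  if (min(pred_probs) < -1e-6 || max(pred_probs) > 1 + 1e-6)
    stop("pred_probs must be probabilities")
  d3 <- dim(pred_probs)[1:3]
  if (is.null(w_near)) w_near <- array(1, d3)
  if (is.null(w_far)) w_far <- array(1, d3)
  near <- weighted_ce_score(pred_probs, target_onehot, w_near)
  far <- weighted_ce_score(pred_probs, target_onehot, w_far)
  loss <- 1 - (beta * near$C + (1 - beta) * far$C)
  out <- list(loss = loss, C = near$C, C_rev = far$C)
  if (!is.null(logits)) {
    n <- prod(d3)
    P <- matrix(pred_probs, n, dim(pred_probs)[4])
    Y <- matrix(target_onehot, n, dim(target_onehot)[4])
    gz <- (beta * near$C * near$wn + (1 - beta) * far$C * far$wn) * (P - Y)
    out$grad_logits <- array(gz, dim(pred_probs))
  }
  out
}

#' Inverse-frequency class-balancing weights
#'
#' `K_c = (1 / N_c) / sum_i (1 / N_i)`; the weights sum to one and are
#' invariant to rescaling all counts.
#'
#' @param counts positive per-class case counts (or frequencies).
#' @return An `xcel_class_weights` list with `K`, `counts`, `n_classes`.
#' @export
class_weights <- function(counts) {
  if (any(counts <= 0))
    stop("class balancing is undefined for zero counts")
  K <- (1 / counts) / sum(1 / counts)
  structure(list(K = K, counts = counts, n_classes = length(counts)),
            class = "xcel_class_weights")
}

#' Class-balanced classification loss over the three condition heads
#'
#' Per-sample categorical (osteophyte, joint space) or binary (alignment)
#' cross-entropy, each multiplied by the balancing weight of the sample's
#' true class; the batch loss per task is the mean, and the total is the sum
#' over the three tasks.
#'
#' @param heads list with per-head `probs` (as returned by the network
#'   forward) for one sample.
#' @param truth a [condition_labels()].
#' @param weights list with `os`, `js`, `hsa` [class_weights()] tables.
#' @param clamp probability floor before taking logs.
#' @return list with `total` and per-task losses.
#' @export
classification_loss <- function(heads, truth, weights, clamp = 1e-12) {
  p_os <- heads$os$probs[truth$os_grade + 1]
  p_js <- heads$js$probs[truth$js_grade + 1]
  p_hsa <- if (truth$hsa == 1) heads$hsa$probs else 1 - heads$hsa$probs
  if (min(p_os, p_js, p_hsa) < clamp)
    warning("true-class probability clamped")
  l_os <- weights$os$K[truth$os_grade + 1] * -log(max(p_os, clamp))
  l_js <- weights$js$K[truth$js_grade + 1] * -log(max(p_js, clamp))
  l_hsa <- weights$hsa$K[truth$hsa + 1] * -log(max(p_hsa, clamp))
  list(total = l_os + l_js + l_hsa, os = l_os, js = l_js, hsa = l_hsa)
}

# Gradients of the class-balanced loss with respect to head logits for one
# sample: softmax heads give K_true * (p - y); the sigmoid head gives
# K_true * (p - y).
classification_loss_grads <- function(heads, truth, weights) {
  y_os <- replace(numeric(3), truth$os_grade + 1, 1)
  y_js <- replace(numeric(3), truth$js_grade + 1, 1)
  list(os_logits = weights$os$K[truth$os_grade + 1] *
         (heads$os$probs - y_os),
       js_logits = weights$js$K[truth$js_grade + 1] *
         (heads$js$probs - y_js),
       hsa_logits = weights$hsa$K[truth$hsa + 1] *
         (heads$hsa$probs - truth$hsa))
}
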