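#' Training configuration
#'
#' @param lr ADAM learning rate.
#' @param batch_size samples per optimizer step.
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience: training stops after this many
#'   consecutive epochs without validation-loss improvement.
#' @param val_fraction fraction of cases held out for validation (at least
#'   one case).
#' @param seed seed controlling the split, shuffling and initialization.
#' @param freeze_setup stage-2 regime name ("TL", "FT-B", "FT-E", "FT-N").
#' @param gamma,tau distance-weight-map parameters (see
#'   [distance_weight_maps()]).
#' @return An `xcel_train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 2L, max_epochs = 100L,
                         patience = 40L, val_fraction = 0.15, seed = 1L,
                         freeze_setup = "FT-E", gamma = 5, tau = 3) {
  stopifnot(lr > 0, patience >= 1, batch_size >= 1, max_epochs >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 freeze_setup = freeze_setup, gamma = gamma, tau = tau),
            class = "xcel_train_config")
}

#' Split cases into train and test sets
#'
#' The test set size is `round(n * test_frac)` (e.g. 86 of 571 cases at the
#' default 15%).
#'
#' @param n number of cases.
#' @param test_frac held-out fraction.
#' @param seed shuffling seed.
#' @return list with `train` and `test` index vectors.
#' @export
train_test_split <- function(n, test_frac = 0.15, seed = 1L) {
  n_test <- round(n * test_frac)
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n - n_test)]),
       test = sort(idx[n - n_test + seq_len(n_test)]))
}

# ---- ADAM over parameter trees -----------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update_tree <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                             eps = 1e-8) {
  if (is.numeric(p)) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
  }
  keys <- if (!is.null(names(p))) names(p) else seq_along(p)
  for (i in keys) {
    r <- adam_update_tree(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
    p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
  }
  list(p = p, m = m, v = v)
}

adam_step <- function(model, grads, state, lr) {
  state$t <- state$t + 1L
  for (grp in names(model$params)) {
    if (!model$trainable[[grp]]) next
    r <- adam_update_tree(model$params[[grp]], grads[[grp]],
                          state$m[[grp]], state$v[[grp]], lr, state$t)
    model$params[[grp]] <- r$p
    state$m[[grp]] <- r$m
    state$v[[grp]] <- r$v
  }
  list(model = model, state = state)
}

tree_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  keys <- if (!is.null(names(a))) names(a) else seq_along(a)
  for (i in keys) a[[i]] <- tree_add(a[[i]], b[[i]])
  a
}
tree_scale <- function(a, k) {
  if (is.numeric(a)) return(a * k)
  lapply(a, tree_scale, k = k)
}

make_batches <- function(idx, batch_size) {
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# ---- stage 1: segmentation ---------------------------------------------------

#' Train the segmentation module (encoder + both decoders)
#'
#' Minimizes the sum of the region loss (scheduled Dice weight, see
#' [alpha_schedule()]) and the contour loss (per-batch boundary fraction
#' beta) with ADAM, early-stopping on the validation loss and returning the
#' best-validation weights.
#'
#' @param dseg list of samples, each a list with `ct` (normalized 3D array,
#'   edges divisible by 8) and `labels` (integer array over 0..2).
#' @param cfg a [train_config()].
#' @param model optional pre-built [build_model()]; built from `cfg$seed`
#'   otherwise.
#' @return list with `model` (best weights) and `record` (per-epoch losses,
#'   stopping epoch, config, seed, wall time).
#' @export
train_segmentation <- function(dseg, cfg = train_config(), model = NULL) {
  stopifnot(length(dseg) >= 1)
  t0 <- Sys.time()
  if (is.null(model)) model <- build_model(seed = cfg$seed)
  n <- length(dseg)
  n_val <- max(1L, min(n - 1L, round(cfg$val_fraction * n)))
  idx <- with_seed(cfg$seed + 1L, sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- setdiff(idx, val_idx)
  K <- model$cfg$seg_classes
  prep <- lapply(dseg, function(s) {
    lab <- if (inherits(s$labels, "xcel_labels")) s$labels$data else s$labels
    x <- if (inherits(s$ct, "xcel_ct")) s$ct$data else s$ct
    edges <- edge_targets(lab)
    wm <- distance_weight_maps(lab, gamma = cfg$gamma, tau = cfg$tau)
    list(x = x, y = one_hot(lab, K), ye = one_hot(edges, K),
         w_near = wm$w_near, w_far = wm$w_far,
         n_edge = sum(edges > 0), n_vox = length(edges))
  })
  sample_loss <- function(i, alpha, beta, want_grads = FALSE) {
    s <- prep[[i]]
    fw <- nn_forward(model, s$x, seg = TRUE, cls = FALSE, keep = want_grads)
    lr_ <- region_loss(fw$md_probs, s$y, alpha, s$w_near,
                       logits = if (want_grads) fw$md_logits)
    lc_ <- contour_loss(fw$cd_probs, s$ye, beta, s$w_near, s$w_far,
                        logits = if (want_grads) fw$cd_logits)
    loss <- lr_$loss + lc_$loss
    if (!is.finite(loss))
      stop(sprintf("non-finite loss at sample %d (L_r=%g, L_c=%g)",
                   i, lr_$loss, lc_$loss))
    out <- list(loss = loss, dice = lr_$dice)
    if (want_grads)
      out$grads <- nn_backward(model, fw$cache,
                               list(md_logits = lr_$grad_logits,
                                    cd_logits = lc_$grad_logits))
    out
  }
  state <- adam_init(model$params)
  rec <- list(train_loss = numeric(0), val_loss = numeric(0),
              train_dice = numeric(0), alpha = numeric(0))
  best <- list(loss = Inf, epoch = 0L, params = model$params)
  set.seed(cfg$seed + 2L)
  epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    alpha <- alpha_schedule(epoch - 1L)
    order_ <- sample(tr_idx)
    ep_loss <- 0; ep_dice <- 0; ns <- 0
    for (batch in make_batches(order_, cfg$batch_size)) {
      beta <- sum(vapply(prep[batch], `[[`, 1, "n_edge")) /
        sum(vapply(prep[batch], `[[`, 1, "n_vox"))
      acc <- NULL
      for (i in batch) {
        r <- sample_loss(i, alpha, beta, want_grads = TRUE)
        ep_loss <- ep_loss + r$loss; ep_dice <- ep_dice + r$dice
        ns <- ns + 1
        g <- tree_scale(r$grads, 1 / length(batch))
        acc <- if (is.null(acc)) g else tree_add(acc, g)
      }
      st <- adam_step(model, acc, state, cfg$lr)
      model <- st$model; state <- st$state
    }
    vl <- mean(vapply(val_idx, function(i) {
      beta <- prep[[i]]$n_edge / prep[[i]]$n_vox
      sample_loss(i, alpha, beta)$loss
    }, 1))
    rec$train_loss <- c(rec$train_loss, ep_loss / ns)
    rec$train_dice <- c(rec$train_dice, ep_dice / ns)
    rec$val_loss <- c(rec$val_loss, vl)
    rec$alpha <- c(rec$alpha, alpha)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, epoch = epoch, params = model$params)
    } else if (epoch - best$epoch >= cfg$patience) break
  }
  model$params <- best$params
  rec$best_epoch <- best$epoch
  rec$stopping_epoch <- epoch
  rec$seed <- cfg$seed
  rec$config <- unclass(cfg)
  rec$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(model = model, record = rec)
}

# ---- stage 2: classification -------------------------------------------------

#' Train the classification branch under a freeze regime
#'
#' Applies the requested freeze setup to the stage-1 model and minimizes the
#' class-balanced sum of the three condition losses; gradients propagate only
#' as deep as the regime re-trains (nothing below the classification branch
#' for TL, down to the bottleneck for FT-B, through the encoder for
#' FT-E/FT-N). The optimizer is re-instantiated (no stage-1 moments).
#'
#' @param model stage-1 `xcel_model`.
#' @param dcls list of samples, each with `crop` (normalized array, edges
#'   divisible by 8) and `truth` ([condition_labels()]).
#' @param cfg a [train_config()]; `cfg$freeze_setup` picks the regime.
#' @param weights optional list of `os`, `js`, `hsa` [class_weights()];
#'   computed from the training-label counts otherwise.
#' @return list with `model`, `record`, and the class `weights` used.
#' @export
train_classification <- function(model, dcls, cfg = train_config(),
                                 weights = NULL) {
  stopifnot(length(dcls) >= 1)
  t0 <- Sys.time()
  model <- apply_freeze(model, cfg$freeze_setup)
  backbone <- switch(cfg$freeze_setup, "TL" = "none", "FT-B" = "bottleneck",
                     "full")
  for (s in dcls)
    if (is.null(s$truth)) stop("every classification sample needs truth labels")
  if (is.null(weights)) {
    cnt <- function(get, k) {
      v <- vapply(dcls, get, 1L)
      tabulate(v + 1L, k)
    }
    weights <- list(os = class_weights(cnt(function(s) s$truth$os_grade, 3)),
                    js = class_weights(cnt(function(s) s$truth$js_grade, 3)),
                    hsa = class_weights(cnt(function(s) s$truth$hsa, 2)))
  }
  n <- length(dcls)
  n_val <- max(1L, min(n - 1L, round(cfg$val_fraction * n)))
  idx <- with_seed(cfg$seed + 3L, sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- setdiff(idx, val_idx)
  state <- adam_init(model$params)
  rec <- list(train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, epoch = 0L, params = model$params)
  set.seed(cfg$seed + 4L)
  epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    order_ <- sample(tr_idx)
    ep_loss <- 0; ns <- 0
    for (batch in make_batches(order_, cfg$batch_size)) {
      acc <- NULL
      for (i in batch) {
        s <- dcls[[i]]
        fw <- nn_forward(model, s$crop, seg = FALSE, cls = TRUE, keep = TRUE)
        l <- classification_loss(fw$heads, s$truth, weights)
        if (!is.finite(l$total))
          stop(sprintf("non-finite classification loss at sample %d", i))
        ep_loss <- ep_loss + l$total; ns <- ns + 1
        gl <- classification_loss_grads(fw$heads, s$truth, weights)
        g <- nn_backward(model, fw$cache, gl, backbone = backbone)
        g <- tree_scale(g, 1 / length(batch))
        acc <- if (is.null(acc)) g else tree_add(acc, g)
      }
      st <- adam_step(model, acc, state, cfg$lr)
      model <- st$model; state <- st$state
    }
    vl <- mean(vapply(val_idx, function(i) {
      fw <- nn_forward(model, dcls[[i]]$crop, seg = FALSE, cls = TRUE)
      classification_loss(fw$heads, dcls[[i]]$truth, weights)$total
    }, 1))
    rec$train_loss <- c(rec$train_loss, ep_loss / ns)
    rec$val_loss <- c(rec$val_loss, vl)
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, epoch = epoch, params = model$params)
    } else if (epoch - best$epoch >= cfg$patience) break
  }
  model$params <- best$params
  rec$best_epoch <- best$epoch
  rec$stopping_epoch <- epoch
  rec$seed <- cfg$seed
  rec$config <- unclass(cfg)
  rec$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(model = model, record = rec, weights = weights)
}

#' Predict conditions from classification heads
#'
#' Argmax for the 3-way heads; 0.5 sigmoid threshold for alignment.
#' @param heads head outputs from the network forward pass.
#' @return a [condition_labels()].
#' @export
heads_to_conditions <- function(heads) {
  condition_labels(which.max(heads$os$probs) - 1L,
                   which.max(heads$js$probs) - 1L,
                   as.integer(heads$hsa$probs >= 0.5))
}

#' End-to-end inference on a normalized CT volume
#'
#' Patches the volume, runs the mask decoder on each patch, stitches the
#' class probabilities (mean over overlaps, renormalized) and takes the
#' per-voxel argmax; then extracts the glenohumeral crop from the predicted
#' labels and runs the classification heads. If the segmentation finds no
#' humerus or no scapula, classification is skipped with an explicit status.
#'
#' @param model trained `xcel_model`.
#' @param ct normalized [ct_volume()].
#' @param patch_edge patch size; defaults to the largest multiple of 8 not
#'   exceeding min(volume edge, 160).
#' @param crop_edge GH crop size for the classification pass.
#' @return list with `labels` ([label_volume()]), `conditions`
#'   ([condition_labels()] or NULL), `probs`, and `status`.
#' @export
predict_volume <- function(model, ct, patch_edge = NULL, crop_edge = 80L) {
  stopifnot(inherits(ct, "xcel_ct"))
  if (ct$units != "normalized") stop("normalize the volume first")
  d <- dim(ct$data)
  if (is.null(patch_edge))
    patch_edge <- max(8L, 8L * (min(c(d, 160L)) %/% 8L))
  ps <- extract_patches(ct$data, patch_edge)
  for (i in seq_along(ps$patches)) {
    fw <- nn_forward(model, ps$patches[[i]]$data, seg = TRUE, cls = FALSE)
    ps$patches[[i]]$data <- fw$md_probs
  }
  probs <- stitch_patches(ps)
  # undo symmetric padding if any
  if (any(ps$pad_lo > 0) || any(ps$source_shape != d)) {
    probs <- probs[ps$pad_lo[1] + seq_len(d[1]),
                   ps$pad_lo[2] + seq_len(d[2]),
                   ps$pad_lo[3] + seq_len(d[3]), , drop = FALSE]
  }
  lab <- array(max.col(matrix(probs, prod(d), dim(probs)[4])) - 1L, d)
  labels <- label_volume(lab, ct$spacing_mm)
  if (!any(lab == 1L) || !any(lab == 2L)) {
    return(list(labels = labels, conditions = NULL, probs = probs,
                status = "no GH joint found"))
  }
  crop <- extract_gh_crop(ct, labels, crop_edge)
  fw <- nn_forward(model, crop$vol, seg = FALSE, cls = TRUE)
  list(labels = labels, conditions = heads_to_conditions(fw$heads),
       probs = probs, status = "ok")
}
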