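#' Network configuration
#'
#' The backbone is a 3-block volumetric encoder (two 3x3x3 convolutions with
#' ReLU per block, then 2x2x2 max pooling) whose feature maps start at eight
#' channels and double per block, a 64-channel bottleneck, and two parallel
#' transpose-convolution decoders: the mask decoder (MD) predicting region
#' labels and the contour decoder (CD) predicting class boundaries. Encoder
#' skip connections feed both decoders, and each CD block output is
#' additionally concatenated into the same-resolution MD block input
#' (unidirectional CD to MD skips). The classification path applies global
#' average pooling to the bottleneck, two dense layers (64 and 16 units,
#' ReLU), and three heads: 3-way softmax for osteophyte size, 3-way softmax
#' for joint space, and a single sigmoid unit for humeroscapular alignment.
#'
#' @param in_channels input channels (1 for CT).
#' @param base_filters encoder filters in the first block (doubled per block).
#' @param n_blocks number of encoder blocks / poolings.
#' @param seg_classes segmentation output channels (background, humerus,
#'   scapula).
#' @param dense_units classification dense-layer widths.
#' @return An `xcel_net_config`.
#' @export
network_config <- function(in_channels = 1L, base_filters = 8L, n_blocks = 3L,
                           seg_classes = 3L, dense_units = c(64L, 16L)) {
  cfg <- list(in_channels = as.integer(in_channels),
              base_filters = as.integer(base_filters),
              n_blocks = as.integer(n_blocks),
              seg_classes = as.integer(seg_classes),
              dense_units = as.integer(dense_units),
              heads = c(os = 3L, js = 3L, hsa = 1L))
  cfg$channels <- as.integer(cfg$base_filters * 2^(0:(cfg$n_blocks - 1L)))
  cfg$bottleneck_channels <- as.integer(cfg$base_filters * 2^cfg$n_blocks)
  class(cfg) <- "xcel_net_config"
  cfg
}

conv_param <- function(k, cin, cout) {
  list(W = array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
                 c(k, k, k, cin, cout)),
       b = numeric(cout))
}
dense_param <- function(nin, nout) {
  list(W = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

#' Build the dual-task model
#'
#' @param cfg a [network_config()].
#' @param seed seed for He-style weight initialization.
#' @return An `xcel_model` with fields `params`, `cfg` and per-group
#'   `trainable` flags (encoder, bottleneck, decoders, classification).
#' @export
build_model <- function(cfg = network_config(), seed = 1L) {
  ch <- cfg$channels
  nb <- cfg$n_blocks
  bc <- cfg$bottleneck_channels
  params <- with_seed(seed, {
    enc <- lapply(seq_len(nb), function(b) {
      cin <- if (b == 1) cfg$in_channels else ch[b - 1]
      list(conv1 = conv_param(3, cin, ch[b]),
           conv2 = conv_param(3, ch[b], ch[b]))
    })
    bott <- list(conv1 = conv_param(3, ch[nb], bc),
                 conv2 = conv_param(3, bc, bc))
    mk_dec <- function(extra_mult) {
      up <- lapply(seq_len(nb), function(l) {
        cin <- if (l == nb) bc else ch[l + 1]
        list(W = array(rnorm(8 * cin * ch[l], sd = sqrt(2 / (8 * cin))),
                       c(2, 2, 2, cin, ch[l])),
             b = numeric(ch[l]))
      })
      block <- lapply(seq_len(nb), function(l)
        list(conv1 = conv_param(3, (1 + 1 + extra_mult) * ch[l], ch[l]),
             conv2 = conv_param(3, ch[l], ch[l])))
      list(up = up, block = block,
           head = dense_param(ch[1], cfg$seg_classes))
    }
    cd <- mk_dec(0L)
    md <- mk_dec(1L)
    du <- cfg$dense_units
    cls <- list(dense1 = dense_param(bc, du[1]),
                dense2 = dense_param(du[1], du[2]),
                os = dense_param(du[2], cfg$heads[["os"]]),
                js = dense_param(du[2], cfg$heads[["js"]]),
                hsa = dense_param(du[2], cfg$heads[["hsa"]]))
    list(encoder = enc, bottleneck = bott,
         decoders = list(cd = cd, md = md), classification = cls)
  })
  structure(list(params = params, cfg = cfg,
                 trainable = c(encoder = TRUE, bottleneck = TRUE,
                               decoders = TRUE, classification = TRUE)),
            class = "xcel_model")
}

#' Table of freeze regimes for stage-2 training
#'
#' TL freezes the whole segmentation backbone and trains only the
#' classification branch; FT-B additionally re-trains the bottleneck, FT-E
#' the encoder and bottleneck, FT-N the entire network.
#'
#' @param name one of "TL", "FT-B", "FT-E", "FT-N".
#' @return named logical vector of trainable flags per parameter group.
#' @export
freeze_setup <- function(name = c("TL", "FT-B", "FT-E", "FT-N")) {
  name <- match.arg(name)
  switch(name,
    "TL"   = c(encoder = FALSE, bottleneck = FALSE, decoders = FALSE,
               classification = TRUE),
    "FT-B" = c(encoder = FALSE, bottleneck = TRUE, decoders = FALSE,
               classification = TRUE),
    "FT-E" = c(encoder = TRUE, bottleneck = TRUE, decoders = FALSE,
               classification = TRUE),
    "FT-N" = c(encoder = TRUE, bottleneck = TRUE, decoders = TRUE,
               classification = TRUE))
}

#' Apply a freeze regime to a model
#' @param model an `xcel_model`.
#' @param setup regime name (see [freeze_setup()]) or a named logical vector.
#' @return the model with updated `trainable` flags.
#' @export
apply_freeze <- function(model, setup) {
  if (is.character(setup)) setup <- freeze_setup(setup)
  stopifnot(setequal(names(setup),
                     c("encoder", "bottleneck", "decoders", "classification")))
  if (!setup[["classification"]])
    stop("the classification branch is always trainable in stage 2")
  model$trainable <- setup[names(model$trainable)]
  model
}

# ---- flatten / tree utilities ------------------------------------------------

flatten_params <- function(tree, prefix = "") {
  if (is.numeric(tree)) {
    out <- list(tree)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  for (nm in names(tree))
    out <- c(out, flatten_params(tree[[nm]],
                                 if (prefix == "") nm
                                 else paste(prefix, nm, sep = ".")))
  out
}

assign_flat <- function(tree, flat) {
  for (nm in names(flat)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tree[[path]] <- flat[[nm]]
  }
  tree
}

# Lists use positional names "1","2",... so flatten paths are invertible.
name_positions <- function(tree) {
  if (!is.list(tree)) return(tree)
  if (is.null(names(tree))) names(tree) <- as.character(seq_along(tree))
  lapply(tree, name_positions)
}

#' Count parameters per group
#' @param model an `xcel_model`.
#' @return named integer vector over the four parameter groups.
#' @export
parameter_counts <- function(model) {
  vapply(model$params, function(g)
    sum(vapply(flatten_params(name_positions(g)), length, 1L)),
    1L)
}

#' Hash the weights of one parameter group
#'
#' Used to audit that frozen groups are bit-identical across training.
#' @param model an `xcel_model`.
#' @param group one of "encoder", "bottleneck", "decoders", "classification".
#' @return md5 string.
#' @export
param_group_hash <- function(model, group = names(model$params)) {
  vapply(match.arg(group, several.ok = TRUE), function(g)
    object_hash(model$params[[g]]), "")
}

# ---- forward -----------------------------------------------------------------

conv_fwd <- function(x, p) cpp_conv3d_fwd(x, p$W, p$b)

conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  y <- m %*% p$W
  y <- sweep(y, 2, p$b, `+`)
  array(y, c(d[1:3], ncol(p$W)))
}

cat_channels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:3]
  array(unlist(xs, use.names = FALSE),
        c(d, sum(vapply(xs, function(x) dim(x)[4], 1))))
}

softmax_channels <- function(z) {
  d <- dim(z)
  m <- matrix(z, prod(d[1:3]), d[4])
  mx <- m[, 1]
  for (c in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, c])
  m <- exp(m - mx)
  array(m / rowSums(m), d)
}

softmax_vec <- function(z) {
  z <- exp(z - max(z))
  z / sum(z)
}

# Full forward pass. `x` is a 3D array with every edge divisible by
# 2^n_blocks. Returns outputs plus (optionally) the activation cache needed
# by nn_backward.
nn_forward <- function(model, x, seg = TRUE, cls = TRUE, keep = FALSE) {
  cfg <- model$cfg
  p <- model$params
  nb <- cfg$n_blocks
  d <- dim(x)
  if (any(d %% 2^nb != 0))
    stop(sprintf("input edges %s must be divisible by %d",
                 paste(d, collapse = "x"), 2^nb))
  h <- array(x, c(d, 1L))
  cache <- list(x = h, enc = vector("list", nb))
  for (b in seq_len(nb)) {
    a1 <- relu(conv_fwd(h, p$encoder[[b]]$conv1))
    a2 <- relu(conv_fwd(a1, p$encoder[[b]]$conv2))
    pl <- cpp_maxpool3d_fwd(a2)
    cache$enc[[b]] <- list(input = h, a1 = a1, a2 = a2, idx = pl$idx,
                           dim_in = dim(a2))
    h <- pl$out
  }
  a1 <- relu(conv_fwd(h, p$bottleneck$conv1))
  A <- relu(conv_fwd(a1, p$bottleneck$conv2))
  cache$bott <- list(input = h, a1 = a1, A = A)
  out <- list(bottleneck = A)

  if (cls) {
    nz <- prod(dim(A)[1:3])
    pooled <- colSums(matrix(A, nz, dim(A)[4])) / nz
    d1 <- relu(drop(crossprod(p$classification$dense1$W, pooled)) +
                 p$classification$dense1$b)
    d2 <- relu(drop(crossprod(p$classification$dense2$W, d1)) +
                 p$classification$dense2$b)
    logit <- function(hd) drop(crossprod(hd$W, d2)) + hd$b
    os_l <- logit(p$classification$os)
    js_l <- logit(p$classification$js)
    hsa_l <- logit(p$classification$hsa)
    cache$cls <- list(pooled = pooled, d1 = d1, d2 = d2)
    out$heads <- list(
      os = list(logits = os_l, probs = softmax_vec(os_l)),
      js = list(logits = js_l, probs = softmax_vec(js_l)),
      hsa = list(logits = hsa_l, probs = stats::plogis(hsa_l)))
  }

  if (seg) {
    dec_fwd <- function(br, extra) {
      hh <- A
      lev <- vector("list", nb)
      for (l in seq(nb, 1)) {
        up <- cpp_upconv3d_fwd(hh, br$up[[l]]$W, br$up[[l]]$b)
        cc <- if (is.null(extra)) cat_channels(up, cache$enc[[l]]$a2)
              else cat_channels(up, cache$enc[[l]]$a2, extra[[l]]$a2)
        b1 <- relu(conv_fwd(cc, br$block[[l]]$conv1))
        b2 <- relu(conv_fwd(b1, br$block[[l]]$conv2))
        lev[[l]] <- list(input = hh, up = up, cat = cc, a1 = b1, a2 = b2)
        hh <- b2
      }
      logits <- conv1x1_fwd(hh, br$head)
      list(lev = lev, logits = logits)
    }
    cd <- dec_fwd(p$decoders$cd, NULL)
    md <- dec_fwd(p$decoders$md, cd$lev)
    cache$cd <- cd$lev
    cache$md <- md$lev
    out$cd_logits <- cd$logits
    out$md_logits <- md$logits
    out$cd_probs <- softmax_channels(cd$logits)
    out$md_probs <- softmax_channels(md$logits)
  }
  if (keep) out$cache <- cache
  out
}

# ---- backward ----------------------------------------------------------------

zero_like <- function(tree) {
  if (is.numeric(tree)) return(array(0, dim(tree) %||% length(tree)))
  lapply(tree, zero_like)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

conv_bwd <- function(x, p, gy, need_gx = TRUE) {
  cpp_conv3d_bwd(x, p$W, gy, need_gx)
}

conv1x1_bwd <- function(x, p, gy) {
  d <- dim(x)
  n <- prod(d[1:3])
  mX <- matrix(x, n, d[4])
  mG <- matrix(gy, n, ncol(p$W))
  list(gx = array(mG %*% t(p$W), d),
       gw = crossprod(mX, mG), gb = colSums(mG))
}

relu_bwd <- function(g, a) cpp_relu_bwd(g, a)

split_channels <- function(g, sizes) {
  d <- dim(g)
  out <- vector("list", length(sizes))
  at <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- g[, , , at + seq_len(sizes[i]), drop = FALSE]
    at <- at + sizes[i]
  }
  out
}

# Backward pass over the cached forward. `gout` may contain gradients with
# respect to md_logits / cd_logits (arrays) and os/js/hsa logits (vectors).
# `backbone` controls how deep classification-side gradients propagate:
# "none" stops at the classification branch, "bottleneck" includes the
# bottleneck convolutions, "full" reaches the encoder as well. Segmentation
# gradients (when present) always traverse the full backbone.
nn_backward <- function(model, cache, gout, backbone = "full") {
  cfg <- model$cfg
  p <- model$params
  nb <- cfg$n_blocks
  g <- list(encoder = zero_like(p$encoder),
            bottleneck = zero_like(p$bottleneck),
            decoders = zero_like(p$decoders),
            classification = zero_like(p$classification))
  A <- cache$bott$A
  gA <- array(0, dim(A))
  have_seg <- !is.null(gout$md_logits) || !is.null(gout$cd_logits)
  skip_g <- lapply(seq_len(nb), function(l) array(0, dim(cache$enc[[l]]$a2)))

  if (!is.null(gout$os_logits) || !is.null(gout$js_logits) ||
      !is.null(gout$hsa_logits)) {
    cl <- cache$cls
    gd2 <- numeric(length(cl$d2))
    for (hd in c("os", "js", "hsa")) {
      gl <- gout[[paste0(hd, "_logits")]]
      if (is.null(gl)) next
      g$classification[[hd]]$W <- outer(cl$d2, gl)
      g$classification[[hd]]$b <- gl
      gd2 <- gd2 + drop(p$classification[[hd]]$W %*% gl)
    }
    gd2 <- relu_bwd(gd2, cl$d2)
    g$classification$dense2$W <- outer(cl$d1, gd2)
    g$classification$dense2$b <- gd2
    gd1 <- relu_bwd(drop(p$classification$dense2$W %*% gd2), cl$d1)
    g$classification$dense1$W <- outer(cl$pooled, gd1)
    g$classification$dense1$b <- gd1
    if (backbone != "none") {
      gpool <- drop(p$classification$dense1$W %*% gd1)
      nz <- prod(dim(A)[1:3])
      gA <- gA + array(rep(gpool / nz, each = nz), dim(A))
    }
  }

  if (have_seg) {
    dec_bwd <- function(br, lev, glogits, gextra_out, gprev_extra = NULL) {
      # head
      hb <- conv1x1_bwd(lev[[1]]$a2, br$head, glogits)
      gb <- list(head = list(W = hb$gw, b = hb$gb),
                 up = vector("list", nb), block = vector("list", nb))
      gh <- hb$gx
      for (l in seq_len(nb)) {
        gh <- gh + (if (!is.null(gprev_extra)) gprev_extra[[l]]
                    else array(0, dim(lev[[l]]$a2)))
        gh <- relu_bwd(gh, lev[[l]]$a2)
        c2 <- conv_bwd(lev[[l]]$a1, br$block[[l]]$conv2, gh)
        g1 <- relu_bwd(c2$gx, lev[[l]]$a1)
        c1 <- conv_bwd(lev[[l]]$cat, br$block[[l]]$conv1, g1)
        gb$block[[l]] <- list(conv1 = list(W = c1$gw, b = c1$gb),
                              conv2 = list(W = c2$gw, b = c2$gb))
        nchan <- dim(lev[[l]]$up)[4]
        parts <- if (is.null(gextra_out))
          split_channels(c1$gx, c(nchan, nchan))
        else split_channels(c1$gx, c(nchan, nchan, nchan))
        skip_g[[l]] <<- skip_g[[l]] + parts[[2]]
        if (!is.null(gextra_out))
          gextra_out[[l]] <- parts[[3]]
        ub <- cpp_upconv3d_bwd(lev[[l]]$input, br$up[[l]]$W, parts[[1]])
        gb$up[[l]] <- list(W = ub$gw, b = ub$gb)
        gh <- ub$gx
        if (l == nb) gA <<- gA + gh
      }
      list(g = gb, gextra = gextra_out)
    }
    zl <- if (!is.null(gout$md_logits)) gout$md_logits
          else array(0, c(dim(cache$md[[1]]$a2)[1:3], cfg$seg_classes))
    gext <- lapply(seq_len(nb), function(l) array(0, dim(cache$cd[[l]]$a2)))
    mdres <- dec_bwd(p$decoders$md, cache$md, zl, gext)
    g$decoders$md <- mdres$g
    gcl <- if (!is.null(gout$cd_logits)) gout$cd_logits
           else array(0, c(dim(cache$cd[[1]]$a2)[1:3], cfg$seg_classes))
    cdres <- dec_bwd(p$decoders$cd, cache$cd, gcl, NULL,
                     gprev_extra = mdres$gextra)
    g$decoders$cd <- cdres$g
  }

  want_bott <- have_seg || backbone %in% c("bottleneck", "full")
  want_enc <- have_seg || backbone == "full"
  if (want_bott && any(gA != 0)) {
    gA <- relu_bwd(gA, A)
    c2 <- conv_bwd(cache$bott$a1, p$bottleneck$conv2, gA)
    g1 <- relu_bwd(c2$gx, cache$bott$a1)
    c1 <- conv_bwd(cache$bott$input, p$bottleneck$conv1, g1,
                   need_gx = want_enc)
    g$bottleneck <- list(conv1 = list(W = c1$gw, b = c1$gb),
                         conv2 = list(W = c2$gw, b = c2$gb))
    if (want_enc) {
      gh <- c1$gx
      for (b in seq(nb, 1)) {
        ec <- cache$enc[[b]]
        ga2 <- cpp_maxpool3d_bwd(ec$idx, gh, as.integer(ec$dim_in)) +
          skip_g[[b]]
        ga2 <- relu_bwd(ga2, ec$a2)
        c2 <- conv_bwd(ec$a1, p$encoder[[b]]$conv2, ga2)
        g1 <- relu_bwd(c2$gx, ec$a1)
        c1 <- conv_bwd(ec$input, p$encoder[[b]]$conv1, g1, need_gx = b > 1)
        g$encoder[[b]] <- list(conv1 = list(W = c1$gw, b = c1$gb),
                               conv2 = list(W = c2$gw, b = c2$gb))
        gh <- c1$gx
      }
    }
  }
  g
}
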