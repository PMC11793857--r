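test_that("Dice score matches closed forms", {
  lab <- array(0L, c(6, 6, 6)); lab[2:4, 2:4, 2:4] <- 1L
  y <- one_hot(lab, 3)
  expect_equal(dice_score(y, y), 1, tolerance = 1e-5)
  # disjoint foregrounds
  lab2 <- array(0L, c(6, 6, 6)); lab2[5:6, 5:6, 5:6] <- 1L
  expect_lt(dice_score(one_hot(lab2, 3), y), 1e-6)
  # prediction covering exactly half the target, no false positives:
  # 2|A n B| / (|A| + |B|) = 2 * 9 / (9 + 18) = 2/3
  lab4 <- array(0L, c(6, 6, 6)); lab4[2:3, 2:4, 2:4] <- 1L  # 18 voxels
  predr <- array(0L, c(6, 6, 6)); predr[2, 2:4, 2:4] <- 1L  # 9-voxel subset
  d <- dice_score(one_hot(predr, 2), one_hot(lab4, 2))
  expect_equal(d, 2 / 3, tolerance = 1e-4)
})

test_that("alpha schedule is the clamped linear decay", {
  expect_identical(alpha_schedule(0), 1)
  expect_identical(alpha_schedule(50), 0.75)
  expect_identical(alpha_schedule(100), 0.5)
  expect_identical(alpha_schedule(250), 0.5)
  ts <- 0:300
  a <- alpha_schedule(ts)
  expect_true(all(diff(a) <= 0))
  expect_true(all(a >= 0.5 & a <= 1))
  expect_error(alpha_schedule(-1), "non-negative")
})

test_that("distance weight maps follow the boundary-band form", {
  lab <- array(0L, c(10, 10, 10)); lab[4:7, 4:7, 4:7] <- 1L
  wm <- distance_weight_maps(lab, spacing_mm = 1, gamma = 5, tau = 3)
  edges <- edge_targets(lab)
  expect_equal(unique(wm$w_near[edges > 0]), 1 + 5)     # d = 0 on boundary
  # complementarity (w_near + w_far = 2 + gamma) and monotone decay with d
  expect_equal(wm$w_near + wm$w_far, array(2 + 5, dim(lab)),
               tolerance = 1e-12)
  ord <- order(wm$d_mm)
  expect_true(all(diff(wm$w_near[ord]) <= 1e-12))
  # analytic far limit of the functional form
  expect_lt(1 + 5 * exp(-12 / 3), 1.1)
  # distances equal a brute-force nearest-boundary search
  bidx <- which(edges > 0, arr.ind = TRUE)
  ridx <- which(array(TRUE, dim(lab)), arr.ind = TRUE)[seq(1, 1000, 37), ]
  for (r in seq_len(nrow(ridx))) {
    p <- ridx[r, ]
    dd <- sqrt(min(colSums((t(bidx) - as.numeric(p))^2)))
    expect_equal(wm$d_mm[p[1], p[2], p[3]], dd, tolerance = 1e-9)
  }
  # single-class volume: uniform maps with a warning
  expect_warning(u <- distance_weight_maps(array(0L, c(4, 4, 4))), "uniform")
  expect_true(all(u$w_near == 1) && all(u$w_far == 1))
})

test_that("edge targets match the exhaustive neighbourhood oracle", {
  expect_true(all(edge_targets(array(0L, c(5, 5, 5))) == 0L))
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  expect_identical(edge_targets(one)[3, 3, 3], 1L)
  set.seed(21)
  lab <- array(0L, c(8, 8, 8))
  lab[2:5, 2:6, 3:6] <- 1L
  lab[6:7, 3:5, 3:5] <- 2L
  expect_identical(edge_targets(lab), brute_edges(lab))
})

test_that("region and contour losses satisfy the analytic identities", {
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L; lab[7:8, , ] <- 2L
  y <- one_hot(lab, 3)
  # perfect one-hot prediction: both losses vanish
  expect_lt(region_loss(y, y, alpha = 0.7)$loss, 1e-5)
  ye <- one_hot(edge_targets(lab), 3)
  expect_lt(contour_loss(ye, ye, beta = 0.4)$loss, 1e-5)
  # alpha = 1 reduces the region loss to 1 - Dice exactly
  set.seed(2)
  z <- array(rnorm(8^3 * 3), c(8, 8, 8, 3))
  pr <- xcelunet:::softmax_channels(z)
  rl <- region_loss(pr, y, alpha = 1)
  expect_equal(rl$loss, 1 - dice_score(pr, y), tolerance = 1e-12)
  # plugging D = 0.8, C = 0.6 into the formula at alpha = 0.5 gives 0.3
  expect_equal(1 - (0.5 * 0.8 + 0.5 * 0.6), 0.3)
  # and the implementation reproduces its own components
  rl2 <- region_loss(pr, y, alpha = 0.5)
  expect_equal(rl2$loss, 1 - (0.5 * rl2$dice + 0.5 * rl2$C), tolerance = 1e-12)
  cl <- contour_loss(pr, ye, beta = 0.3)
  expect_equal(cl$loss, 1 - (0.3 * cl$C + 0.7 * cl$C_rev), tolerance = 1e-12)
})

test_that("region loss decreases as probability mass moves to the target", {
  lab <- array(0L, c(4, 4, 4)); lab[2, 2, 2] <- 1L
  y <- one_hot(lab, 2)
  losses <- vapply(seq(0.1, 3, length.out = 8), function(s) {
    z <- (2 * y - 1) * s   # logits increasingly aligned with the target
    region_loss(xcelunet:::softmax_channels(z), y, alpha = 0.6)$loss
  }, 1)
  expect_true(all(diff(losses) < 0))
})

test_that("region-loss gradients agree with finite differences", {
  set.seed(3)
  lab <- array(0L, c(4, 4, 4)); lab[2:3, 2:3, 2:3] <- 1L
  y <- one_hot(lab, 2)
  wm <- distance_weight_maps(lab)
  z <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  pr <- xcelunet:::softmax_channels(z)
  rl <- region_loss(pr, y, alpha = 0.6, w_near = wm$w_near, logits = z)
  cl <- contour_loss(pr, y, beta = 0.3, w_near = wm$w_near, w_far = wm$w_far,
                     logits = z)
  for (i in sample(length(z), 5)) {
    eps <- 1e-6
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    fd_r <- (region_loss(xcelunet:::softmax_channels(zp), y, 0.6, wm$w_near)$loss -
             region_loss(xcelunet:::softmax_channels(zm), y, 0.6, wm$w_near)$loss) /
      (2 * eps)
    expect_equal(rl$grad_logits[i], fd_r, tolerance = 1e-5)
    fd_c <- (contour_loss(xcelunet:::softmax_channels(zp), y, 0.3, wm$w_near,
                          wm$w_far)$loss -
             contour_loss(xcelunet:::softmax_channels(zm), y, 0.3, wm$w_near,
                          wm$w_far)$loss) / (2 * eps)
    expect_equal(cl$grad_logits[i], fd_c, tolerance = 1e-5)
  }
})

test_that("class-balancing weights follow the inverse-frequency rule", {
  expect_equal(class_weights(c(10, 10))$K, c(0.5, 0.5))
  expect_equal(class_weights(c(7, 7, 7))$K, rep(1 / 3, 3))
  # observed alignment frequencies 56.1 / 43.9 invert to 0.439 / 0.561
  K <- class_weights(c(56.1, 43.9))$K
  expect_equal(round(K, 3), c(0.439, 0.561))
  # normalization and scale invariance over random count vectors
  set.seed(4)
  for (r in 1:50) {
    n <- sample(2:6, 1)
    cnt <- runif(n, 0.5, 500)
    K <- class_weights(cnt)$K
    expect_equal(sum(K), 1, tolerance = 1e-12)
    expect_equal(class_weights(2 * cnt)$K, K, tolerance = 1e-12)
  }
  expect_error(class_weights(c(3, 0)), "zero")
})

test_that("classification loss matches closed forms", {
  w <- list(os = class_weights(c(1, 1, 1)), js = class_weights(c(1, 1, 1)),
            hsa = class_weights(c(1, 1)))
  truth <- condition_labels(1, 2, 1)
  perfect <- list(os = list(probs = c(0, 1, 0)), js = list(probs = c(0, 0, 1)),
                  hsa = list(probs = 1))
  l <- classification_loss(perfect, truth, w)
  expect_equal(l$total, 0, tolerance = 1e-9)
  uniform <- list(os = list(probs = rep(1 / 3, 3)),
                  js = list(probs = rep(1 / 3, 3)), hsa = list(probs = 0.5))
  lu <- classification_loss(uniform, truth, w)
  expect_equal(lu$os, log(3) / 3, tolerance = 1e-12)
  expect_equal(lu$js, log(3) / 3, tolerance = 1e-12)
  expect_equal(lu$hsa, log(2) / 2, tolerance = 1e-12)
  # gradients match finite differences through softmax/sigmoid
  set.seed(5)
  zos <- rnorm(3); zjs <- rnorm(3); zh <- rnorm(1)
  mk <- function(zos, zjs, zh)
    list(os = list(probs = xcelunet:::softmax_vec(zos)),
         js = list(probs = xcelunet:::softmax_vec(zjs)),
         hsa = list(probs = stats::plogis(zh)))
  g <- xcelunet:::classification_loss_grads(mk(zos, zjs, zh), truth, w)
  eps <- 1e-6
  for (i in 1:3) {
    zp <- zos; zp[i] <- zp[i] + eps; zm <- zos; zm[i] <- zm[i] - eps
    fd <- (classification_loss(mk(zp, zjs, zh), truth, w)$os -
           classification_loss(mk(zm, zjs, zh), truth, w)$os) / (2 * eps)
    expect_equal(g$os_logits[i], fd, tolerance = 1e-5)
  }
  fd <- (classification_loss(mk(zos, zjs, zh + eps), truth, w)$hsa -
         classification_loss(mk(zos, zjs, zh - eps), truth, w)$hsa) / (2 * eps)
  expect_equal(g$hsa_logits, fd, tolerance = 1e-5)
})

test_that("boundary fraction equals the edge-voxel share on toy grids", {
  lab <- array(0L, c(6, 6, 6)); lab[3:4, 3:4, 3:4] <- 1L
  expect_equal(boundary_fraction(lab), sum(brute_edges(lab) > 0) / 6^3)
  b <- boundary_fraction(list(lab, array(0L, c(6, 6, 6))))
  expect_gte(b, 0); expect_lte(b, 1)
  expect_equal(b, sum(brute_edges(lab) > 0) / (2 * 6^3))
})
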