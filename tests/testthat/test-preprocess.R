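test_that("HU normalization maps the working range onto [0, 1]", {
  v <- ct_volume(array(c(-2000, -1024, 0, 2500, 3000), c(5, 1, 1)), 1, "HU")
  n <- hu_normalize(v)
  expect_equal(as.vector(n$data),
               c(0, 0, 1024 / 3524, 1, 1), tolerance = 1e-12)
  expect_identical(n$units, "normalized")
  # monotone non-decreasing
  x <- sort(runif(100, -2000, 3000))
  nx <- hu_normalize(ct_volume(array(x, c(100, 1, 1)), 1, "HU"))$data
  expect_true(all(diff(as.vector(nx)) >= 0))
  # refuses double normalization and non-finite voxels
  expect_error(hu_normalize(n), "already normalized")
  bad <- ct_volume(array(c(NA, 1, 2, 3), c(4, 1, 1)), 1, "HU")
  expect_error(hu_normalize(bad), "non-finite")
})

test_that("label cropping matches an exhaustive bounding-box scan", {
  set.seed(11)
  d <- c(17, 13, 15)
  lab <- array(0L, d)
  lab[sample(prod(d), 25)] <- sample(1:2, 25, replace = TRUE)
  vol <- ct_volume(array(rnorm(prod(d)), d), 1, "HU")
  cr <- crop_to_labels(vol, label_volume(lab, 1))
  nz <- which(lab != 0, arr.ind = TRUE)
  lo <- apply(nz, 2, min); hi <- apply(nz, 2, max)
  expect_identical(cr$offset, as.integer(lo))
  expect_identical(dim(cr$vol$data), as.integer(hi - lo + 1))
  # inverse offset mapping restores original coordinates of labelled voxels
  nz2 <- which(cr$labels$data != 0, arr.ind = TRUE)
  back <- sweep(nz2, 2, cr$offset - 1L, `+`)
  expect_setequal(paste(back[, 1], back[, 2], back[, 3]),
                  paste(nz[, 1], nz[, 2], nz[, 3]))
  # full-grid labels give the identity crop; empty labels error
  full <- label_volume(array(1L, d), 1)
  expect_identical(dim(crop_to_labels(vol, full)$vol$data), as.integer(d))
  expect_error(crop_to_labels(vol, label_volume(array(0L, d), 1)), "empty")
})

test_that("patch grids have minimal count, required overlap, full coverage", {
  offs <- xcelunet:::axis_offsets(280, 160, 0.25)
  expect_identical(offs, c(1L, 121L))     # strides of 120 = 25% overlap of 160
  expect_identical(xcelunet:::axis_offsets(160, 160, 0.25), 1L)
  offs3 <- xcelunet:::axis_offsets(400, 160, 0.25)
  expect_length(offs3, 3)
  # voxelwise coverage oracle on a small synthetic axis set
  vol <- array(seq_len(40 * 24 * 24), c(40, 24, 24))
  ps <- extract_patches(vol, patch_edge = 24, min_overlap_frac = 0.25)
  covered <- array(FALSE, dim(vol))
  for (p in ps$patches) {
    o <- p$offset
    covered[o[1]:(o[1] + 23), o[2]:(o[2] + 23), o[3]:(o[3] + 23)] <- TRUE
    # overlap constraint per axis
    expect_identical(p$data,
                     vol[o[1]:(o[1] + 23), o[2]:(o[2] + 23), o[3]:(o[3] + 23)])
  }
  expect_true(all(covered))
  strides <- diff(sort(unique(vapply(ps$patches, function(p) p$offset[1], 1L))))
  expect_true(all(strides <= 0.75 * 24))
  expect_error(extract_patches(vol, patch_edge = 0), "positive")
})

test_that("short axes are symmetrically zero-padded to the patch edge", {
  vol <- array(1, c(10, 24, 24))
  ps <- extract_patches(vol, patch_edge = 24)
  expect_identical(ps$source_shape, c(24L, 24L, 24L))
  expect_identical(ps$pad_lo, c(7L, 0L, 0L))
  expect_equal(sum(ps$patches[[1]]$data), 10 * 24 * 24)
})

test_that("stitching averages overlaps and renormalizes probabilities", {
  # single full-volume patch: identity
  pr <- array(runif(8^3 * 2), c(8, 8, 8, 2))
  pr <- pr / array(rep(apply(pr, 1:3, sum), 2), dim(pr))
  ps <- structure(list(patches = list(list(data = pr, offset = c(1L, 1L, 1L))),
                       patch_edge = 8L, source_shape = c(8L, 8L, 8L),
                       pad_lo = c(0L, 0L, 0L)), class = "xcel_patchset")
  expect_equal(stitch_patches(ps), pr, tolerance = 1e-12)
  # two overlapping patches: plain mean without renormalization
  a <- array(0.2, c(4, 4, 4, 1)); b <- array(0.6, c(4, 4, 4, 1))
  ps2 <- structure(list(patches = list(list(data = a, offset = c(1L, 1L, 1L)),
                                       list(data = b, offset = c(3L, 1L, 1L))),
                        patch_edge = 4L, source_shape = c(6L, 4L, 4L),
                        pad_lo = c(0L, 0L, 0L)), class = "xcel_patchset")
  st <- stitch_patches(ps2, renormalize = FALSE)
  expect_equal(unique(as.vector(st[3:4, , , 1])), 0.4)
  expect_equal(unique(as.vector(st[1:2, , , 1])), 0.2)
  # identical values in the overlap stay unchanged
  ps2$patches[[2]]$data <- a
  st2 <- stitch_patches(ps2, renormalize = FALSE)
  expect_equal(unique(as.vector(st2)), 0.2)
  # uncovered voxels are an error
  ps2$source_shape <- c(9L, 4L, 4L)
  expect_error(stitch_patches(ps2), "uncovered")
})

test_that("GH crop centres on the joint and keeps its shape at borders", {
  p <- small_params(joint_gap_mm = 2, seed = 9L)
  ph <- generate_phantom(p)
  crop <- extract_gh_crop(hu_normalize(ph$ct), ph$labels, crop_edge = 48)
  sc <- xcelunet:::phantom_scene(p)
  glen <- sc$centre - c(sc$r + p$joint_gap_mm, 0, 0)
  true_mid <- (sc$centre + glen) / 2 / p$spacing_mm + 1
  expect_lt(sqrt(sum((crop$centre - true_mid)^2)), 2)
  expect_identical(dim(crop$vol), rep(48L, 3))
  # crop near the volume border still has the contracted shape (zero-padded)
  big <- extract_gh_crop(hu_normalize(ph$ct), ph$labels, crop_edge = 96)
  expect_identical(dim(big$vol), rep(96L, 3))
  # missing scapula label is a precondition failure
  lab1 <- ph$labels
  lab1$data[lab1$data == 2L] <- 0L
  expect_error(extract_gh_crop(hu_normalize(ph$ct), lab1), "scapula")
})

test_that("sagittal flip is an involution that keeps condition labels", {
  ph <- generate_phantom(tiny_params(osteophyte_height_mm = 4,
                                     osteophyte_count = 1L,
                                     eccentric_shift_mm = 3))
  crop <- extract_gh_crop(hu_normalize(ph$ct), ph$labels, crop_edge = 24,
                          truth = ph$truth)
  fl <- sagittal_flip(crop)
  expect_false(identical(fl$vol, crop$vol))
  expect_identical(sagittal_flip(fl)$vol, crop$vol)
  expect_identical(fl$truth, crop$truth)
  n <- dim(crop$vol)[1]
  expect_identical(fl$vol[1, , ], crop$vol[n, , ])
})
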