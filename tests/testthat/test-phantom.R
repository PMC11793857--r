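test_that("phantom generation is bit-deterministic for a fixed seed", {
  p <- small_params(osteophyte_height_mm = 5, osteophyte_count = 2L,
                    joint_gap_mm = 2, seed = 7L)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$humerus_morph_mesh$vertices,
                   b$humerus_morph_mesh$vertices)
})

test_that("zero osteophyte height gives identical humerus surfaces, grade 0", {
  ph <- generate_phantom(small_params(osteophyte_height_mm = 0,
                                      osteophyte_count = 3L))
  expect_identical(ph$humerus_morph_mesh$vertices,
                   ph$humerus_cleared_mesh$vertices)
  expect_identical(ph$truth$os_grade, 0L)
})

test_that("condition truth follows the grading thresholds", {
  ph <- generate_phantom(small_params(
    osteophyte_height_mm = 5, osteophyte_count = 1L,
    joint_gap_mm = 0.5, eccentric_shift_mm = 4))
  expect_identical(ph$truth$os_grade, 1L)   # 3-7 mm
  expect_identical(ph$truth$js_grade, 2L)   # below one voxel: non-detectable
  expect_identical(ph$truth$hsa, 1L)        # eccentric
  # boundary conventions: 3 and 7 mm fall in the middle class
  expect_identical(generate_phantom(small_params(
    osteophyte_height_mm = 3, osteophyte_count = 1L))$truth$os_grade, 1L)
  expect_identical(generate_phantom(small_params(
    osteophyte_height_mm = 7, osteophyte_count = 1L))$truth$os_grade, 1L)
  expect_identical(generate_phantom(small_params(
    osteophyte_height_mm = 8, osteophyte_count = 1L))$truth$os_grade, 2L)
})

test_that("dataset stratification follows the class mix", {
  ph <- generate_dataset(9, class_mix = c(1, 1, 1), params = small_params(),
                         seed = 3L)
  os <- vapply(ph, function(p) p$truth$os_grade, 1L)
  expect_identical(as.vector(table(factor(os, 0:2))), rep(3L, 3))

  ph <- generate_dataset(30, class_mix = c(0.311, 0.361, 0.328),
                         params = small_params(), seed = 4L)
  os <- vapply(ph, function(p) p$truth$os_grade, 1L)
  counts <- as.vector(table(factor(os, 0:2)))
  # largest-remainder quotas of n * (0.311, 0.361, 0.328) = (9.3, 10.8, 9.8)
  expect_true(all(abs(counts - c(9.3, 10.8, 9.8)) <= 1))
  expect_identical(sum(counts), 30L)
})

test_that("a single-phantom dataset is valid", {
  ph <- generate_dataset(1, params = small_params(), seed = 5L)
  expect_length(ph, 1)
  expect_s3_class(ph[[1]], "xcel_phantom")
  expect_true(all(ph[[1]]$labels$data %in% 0:2))
})

test_that("humerus voxel count grows with head radius", {
  counts <- vapply(c(8, 10, 12), function(r) {
    ph <- generate_phantom(small_params(head_radius_mm = r))
    sum(ph$labels$data == 1L)
  }, 1)
  expect_true(all(diff(counts) > 0))
})

test_that("label-to-label clearance matches the joint gap within one voxel", {
  for (gap in c(1.5, 3, 5)) {
    ph <- generate_phantom(small_params(joint_gap_mm = gap))
    d2 <- xcelunet:::cpp_edt3d(ph$labels$data == 2L, ph$labels$spacing_mm)
    mind <- min(d2[ph$labels$data == 1L])
    expect_lt(abs(mind - gap), 1 * ph$labels$spacing_mm[1] + 1e-9)
  }
})

test_that("auto-grading recovers generated osteophyte grades off-boundary", {
  for (s in c(1, 5, 10)) {
    ph <- generate_phantom(small_params(osteophyte_height_mm = s,
                                        osteophyte_count = 2L,
                                        seed = 20L + s))
    al <- os_autolabel(ph$humerus_morph_mesh, ph$humerus_cleared_mesh)
    expect_identical(al$grade, ph$truth$os_grade)
    expect_lt(abs(al$s_o_mm - s), 1.5 * ph$ct$spacing_mm[1])
  }
})

test_that("a too-small grid raises an explicit geometry error", {
  expect_error(generate_phantom(phantom_params(grid_shape = c(24, 24, 24),
                                               head_radius_mm = 12)),
               class = "xcel_geometry_error")
})

test_that("empty class mix is rejected", {
  expect_error(generate_dataset(5, class_mix = c(0, 0, 0)), "class_mix")
  expect_error(generate_dataset(5, class_mix = numeric(0)), "class_mix")
})

test_that("phantom round-trips through NIfTI, PLY and CSV", {
  ph <- generate_phantom(tiny_params(osteophyte_height_mm = 4,
                                     osteophyte_count = 1L))
  dir <- withr::local_tempdir()
  files <- write_phantom(ph, dir, "case1")
  expect_true(all(file.exists(files)))
  ct <- read_nifti_volume(files[["ct"]])
  expect_equal(ct$data, ph$ct$data, tolerance = 1e-6)
  expect_equal(ct$spacing_mm, ph$ct$spacing_mm)
  m <- read_ply(files[["morph"]])
  expect_equal(m$vertices, unname(ph$humerus_morph_mesh$vertices),
               tolerance = 1e-4)
  expect_identical(m$faces, ph$humerus_morph_mesh$faces)
  truth <- read.csv(files[["truth"]])
  expect_identical(truth$os, ph$truth$os_grade)
})
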