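test_that("volume and mask constructors enforce their invariants", {
  a <- array(1:24, c(2, 3, 4))
  v <- volume_image(a, spacing = c(1, 2, 4), origin = c(5, 6, 7))
  expect_s3_class(v, "volume_image")
  expect_error(volume_image(matrix(1, 2, 2)), "3D")
  expect_error(volume_image(a, spacing = c(1, 0, 1)), "positive")
  expect_error(volume_image(a, direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(mask_volume(array(2, c(2, 2, 2))), "0 or 1")
  m <- mask_volume(array(c(0, 1), c(2, 3, 4)))
  expect_true(all(m$data %in% c(0, 1)))
})

test_that("voxel/world coordinate maps invert each other", {
  g <- vol_grid(list(dim = c(10, 12, 8), spacing = c(0.43, 0.43, 4),
                     origin = c(-20, 15, 3),
                     direction = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)))
  idx <- matrix(c(0, 0, 0, 3, 7, 2, 9.5, 1.25, 6), ncol = 3, byrow = TRUE)
  w <- voxel_to_world(g, idx)
  expect_equal(world_to_voxel(g, w), idx, tolerance = 1e-12)
  # origin is the physical position of voxel (0,0,0)
  expect_equal(as.numeric(voxel_to_world(g, matrix(0, 1, 3))), g$origin)
})

test_that("NIfTI write/read round trip preserves data and geometry", {
  set.seed(1)
  v <- volume_image(array(rnorm(2 * 3 * 4, 1500, 100), c(2, 3, 4)),
                    spacing = c(0.43, 0.43, 4), origin = c(-11, 4, 9),
                    units = "ADC 1e-6 mm^2/s")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_lt(max(abs(r$data - v$data)) / max(abs(v$data)), 1e-5)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  expect_equal(r$direction, v$direction, tolerance = 1e-6)
})

test_that("non-3D NIfTI payloads and non-binary masks are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(2, 2, 2, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3D")

  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume_image(array(c(0, 1, 2), c(3, 3, 3))), f2)
  expect_error(read_mask(f2), "0/1")

  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(volume_image(array(c(0, 1), c(3, 3, 2))), f3)
  expect_s3_class(read_mask(f3), "mask_volume")
})

test_that("resampling is exact on the identity, constants and affine ramps", {
  set.seed(2)
  src <- volume_image(array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                      spacing = c(2, 2, 2))
  expect_equal(resample_to_grid(src, vol_grid(src))$data, src$data)

  cv <- volume_image(array(7.5, c(16, 16, 8)), spacing = c(2, 2, 2))
  tg <- vol_grid(list(dim = c(9, 9, 5), spacing = c(3, 3, 3),
                      origin = c(1, 1, 1), direction = diag(3)))
  rc <- resample_to_grid(cv, tg)
  # interior voxels of a constant stay exactly constant
  expect_equal(unique(as.numeric(rc$data[2:7, 2:7, 2:4])), 7.5)

  # 2x downsample of an affine ramp: linear interpolation reproduces
  # degree-1 fields, so interior values equal the analytic ramp
  g <- vol_grid(list(dim = c(16, 16, 8), spacing = c(1, 1, 1),
                     origin = c(0, 0, 0), direction = diag(3)))
  idx <- expand.grid(x = 0:15, y = 0:15, z = 0:7)
  ramp <- volume_image(array(2 * idx$x + 3 * idx$y - idx$z + 5, c(16, 16, 8)))
  tg2 <- vol_grid(list(dim = c(8, 8, 4), spacing = c(2, 2, 2),
                       origin = c(0.5, 0.5, 0.5), direction = diag(3)))
  rr <- resample_to_grid(ramp, tg2)
  idx2 <- expand.grid(x = 0:7, y = 0:7, z = 0:3)
  expected <- array(2 * (2 * idx2$x + 0.5) + 3 * (2 * idx2$y + 0.5) -
                      (2 * idx2$z + 0.5) + 5, c(8, 8, 4))
  expect_equal(rr$data[2:7, 2:7, 2:3], expected[2:7, 2:7, 2:3],
               tolerance = 1e-12)
})

test_that("resampling onto a disjoint grid is a geometry error", {
  v <- volume_image(array(1, c(4, 4, 4)))
  tg <- vol_grid(list(dim = c(4, 4, 4), spacing = c(1, 1, 1),
                      origin = c(100, 100, 100), direction = diag(3)))
  expect_error(resample_to_grid(v, tg), "disjoint")
})
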