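test_that("rigid transform algebra: inverse, composition, Euler round trip", {
  tr <- rigid_from_euler(c(5, -3, 12), c(4, -1, 2), center = c(10, 20, 5))
  inv <- invert_rigid(tr)
  comp <- compose_rigid(inv, tr)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
  pts <- matrix(rnorm(30, 0, 20), 10, 3)
  expect_lt(max(abs(transform_points(comp, pts) - pts)), 1e-9)

  # composition is associative on points
  t2 <- rigid_from_euler(c(-2, 4, 7), c(1, 1, -3), center = c(0, 0, 0))
  t3 <- rigid_from_euler(c(1, 1, 1), c(0, 2, 0), center = c(5, 5, 5))
  lhs <- transform_points(compose_rigid(compose_rigid(tr, t2), t3), pts)
  rhs <- transform_points(compose_rigid(tr, compose_rigid(t2, t3)), pts)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  ang <- edemarec:::euler_zyx_angles(rigid_from_euler(c(5, -3, 12))$rotation)
  expect_equal(ang, c(5, -3, 12), tolerance = 1e-10)

  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("identity transform returns the volume unchanged; unit lattice shift moves indices", {
  set.seed(3)
  v <- volume_image(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(2, 2, 2))
  out <- apply_rigid(v, rigid_transform())
  expect_identical(out$data, v$data)

  # translation by one voxel along x: output(i) = input(i+1)
  tr <- rigid_transform(translation = c(2, 0, 0))
  sh <- apply_rigid(v, tr)
  expect_equal(sh$data[1:7, , ], v$data[2:8, , ], tolerance = 1e-12)

  m <- mask_volume(array(rbinom(8 * 8 * 4, 1, 0.3), c(8, 8, 4)),
                   spacing = c(2, 2, 2))
  shm <- transform_mask(m, tr)
  expect_equal(shm$data[1:7, , ], m$data[2:8, , ])
})

test_that("transform round trip preserves a smooth structure (dice >= 0.99)", {
  # smooth blob thresholded after T then T^-1
  g <- expand.grid(x = 0:39, y = 0:39, z = 0:19)
  r2 <- (g$x - 19.5)^2 + (g$y - 19.5)^2 + ((g$z - 9.5) * 2)^2
  v <- volume_image(array(exp(-r2 / 250), c(40, 40, 20)), spacing = c(2, 2, 2))
  ctr <- c(39, 39, 19)
  tr <- rigid_from_euler(c(0, 0, 7), c(3, -2, 1), center = ctr)
  back <- apply_rigid(apply_rigid(v, tr), invert_rigid(tr))
  d <- dice_coefficient(back$data > 0.5, v$data > 0.5)
  expect_gte(d, 0.99)

  # sphere mask round trip through transform_mask (10-voxel radius)
  sph <- mask_volume(array(as.numeric(r2 <= 100), c(40, 40, 20)),
                     spacing = c(2, 2, 2))
  back_m <- transform_mask(transform_mask(sph, tr), invert_rigid(tr))
  expect_gte(dice_coefficient(back_m, sph), 0.95)
})

test_that("transform serialization round-trips through the 4x4 matrix file", {
  tr <- rigid_from_euler(c(3, 1, -4), c(2.5, 0, -1), center = c(31, 31, 15))
  f <- withr::local_tempfile(fileext = ".txt")
  write_rigid(tr, f)
  rd <- read_rigid(f)
  pts <- matrix(rnorm(30, 0, 30), 10, 3)
  expect_lt(max(abs(transform_points(tr, pts) - transform_points(rd, pts))),
            1e-8)
})

test_that("self-registration returns the identity", {
  spec <- quick_spec(seed = 2)
  v <- generate_phantom(spec)$adc_pre
  est <- estimate_rigid(v, v, stride = 2L, coarse_angles = c(-3, 0, 3),
                        maxit = 150L)
  expect_lt(max(abs(edemarec:::euler_zyx_angles(est$rotation))), 0.1)
  expect_lt(max(abs(est$translation)), 0.1)
})

test_that("registration with empty overlap raises an estimation error", {
  v <- volume_image(array(1, c(6, 6, 6)))
  w <- volume_image(array(1, c(6, 6, 6)), origin = c(1000, 1000, 1000))
  expect_error(estimate_rigid(v, w, smooth_sigma = 0), "non-finite|overlap")
})
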