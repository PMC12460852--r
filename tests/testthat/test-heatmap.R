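slice_masks <- function() {
  tumor <- array(0, c(12, 12, 5))
  edema <- array(0, c(12, 12, 5))
  tumor[5:8, 5:8, 2] <- 1          # area 16 at slice 2
  tumor[4:9, 4:9, 3] <- 1          # area 36 at slice 3 (peak)
  edema[2:11, 2:11, 2] <- 1 - tumor[2:11, 2:11, 2]
  edema[2:11, 2:11, 4] <- 1
  list(tumor = mask_volume(tumor), edema = mask_volume(edema))
}

test_that("slice selection maximises tumor area where edema is present", {
  m <- slice_masks()
  # peak tumor slice (3) has no edema; slice 2 is the best with edema
  expect_equal(select_slice(m$tumor, m$edema), 2)

  # tie in tumor area breaks toward the lower index
  tumor <- array(0, c(12, 12, 5)); edema <- array(0, c(12, 12, 5))
  tumor[5:6, 5:6, 2] <- 1; tumor[5:6, 5:6, 4] <- 1
  edema[1, 1, 2] <- 1; edema[1, 1, 4] <- 1
  expect_equal(select_slice(mask_volume(tumor), mask_volume(edema)), 2)

  none <- mask_volume(array(0, c(12, 12, 5)))
  expect_error(select_slice(none, m$edema), "no slice")
})

test_that("constant ADC gives unit tile values, all positive at 2.408", {
  adc <- volume_image(array(1500, c(12, 12, 3)))
  edema <- array(0, c(12, 12, 3)); edema[3:10, 3:10, 2] <- 1
  hm <- tile_ratio_map(adc, mask_volume(edema), 2, tile_size = 2)
  expect_true(all(abs(hm$tiles$value - 1) < 1e-12))
  expect_true(all(hm$tiles$positive))
  ev <- hm$predicted_mask[edema[, , 2] > 0]
  expect_true(all(ev))
})

test_that("a single 3x-mean voxel makes exactly its tile negative", {
  adc_arr <- array(1000, c(12, 12, 3))
  edema <- array(0, c(12, 12, 3)); edema[3:10, 3:10, 2] <- 1
  # raise one voxel so that the ROI mean stays m and the voxel is 3m
  n_roi <- sum(edema)
  x <- (3 * (n_roi - 1) * 1000) / (n_roi - 3)   # solves max = 3 * new mean
  adc_arr[4, 4, 2] <- x
  adc <- volume_image(adc_arr)
  hm <- tile_ratio_map(adc, mask_volume(edema), 2, tile_size = 2)
  hot <- hm$tiles[hm$tiles$x == 3 & hm$tiles$y == 3, ]
  expect_equal(hot$value, 3, tolerance = 1e-9)
  expect_false(hot$positive)            # 3.0 >= 2.408
  expect_equal(sum(!hm$tiles$positive), 1)
})

test_that("tile values match the loop-based oracle on a phantom slice", {
  cs <- generate_phantom(quick_spec(seed = 6))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  for (k in c(2, 3)) {
    hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = k)
    o <- naive_tile_values(cs$adc_pre$data[, , sl],
                           cs$edema_pre$data[, , sl] > 0, k)
    got <- hm$tiles[order(hm$tiles$x, hm$tiles$y), ]
    o <- o[order(o$x, o$y), ]
    expect_equal(nrow(got), nrow(o))
    expect_equal(got$value, o$value, tolerance = 1e-12)
  }
})

test_that("fractional 2.5-voxel tiles run on the 2x upsampled grid", {
  cs <- generate_phantom(quick_spec(seed = 6))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2.5)
  expect_equal(hm$factor, 2L)
  expect_true(all(diff(sort(unique(hm$tiles$x))) %% 5 == 0))
  expect_equal(dim(hm$predicted_mask), dim(cs$adc_pre$data)[1:2])
  expect_warning(tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 4),
                 "non-standard")
  expect_error(tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2.3),
               "multiples of 0.5")
})

test_that("tiling is a partition: no evaluated cell is claimed twice", {
  cs <- generate_phantom(quick_spec(seed = 16))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2)
  k <- 2
  claimed <- matrix(0L, nrow(hm$value_map), ncol(hm$value_map))
  for (i in seq_len(nrow(hm$tiles))) {
    xr <- hm$tiles$x[i]:min(hm$tiles$x[i] + k - 1, nrow(claimed))
    yr <- hm$tiles$y[i]:min(hm$tiles$y[i] + k - 1, ncol(claimed))
    claimed[xr, yr] <- claimed[xr, yr] + 1L
  }
  expect_true(all(claimed <= 1L))
})

test_that("raising the threshold never shrinks the predicted-positive set", {
  cs <- generate_phantom(quick_spec(seed = 26))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  prev <- 0
  for (thr in c(1.2, 2.408, 4, 10)) {
    hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2,
                         threshold = thr)
    npos <- sum(hm$tiles$positive)
    expect_gte(npos, prev)
    prev <- npos
  }
})

test_that("prediction scoring reproduces its closed forms", {
  cs <- generate_phantom(quick_spec(seed = 2))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2)

  # prediction identical to truth
  hm_perfect <- hm
  hm_perfect$predicted_mask <- cs$truth_infiltration$data[, , sl] > 0
  ev <- evaluate_prediction(hm_perfect, cs$truth_infiltration, cs$edema_pre)
  expect_equal(ev$voxel_accuracy, 1)
  expect_equal(ev$dice, 1)

  # complement of truth restricted to edema
  hm_flip <- hm
  hm_flip$predicted_mask <- !(cs$truth_infiltration$data[, , sl] > 0)
  ev2 <- evaluate_prediction(hm_flip, cs$truth_infiltration, cs$edema_pre)
  expect_equal(ev2$voxel_accuracy, 0)
  expect_equal(ev2$dice, 0)

  # all-positive prediction: accuracy = prevalence, dice = 2p/(1+p)
  hm_all <- hm
  hm_all$predicted_mask <- matrix(TRUE, nrow(hm$predicted_mask),
                                  ncol(hm$predicted_mask))
  ev3 <- evaluate_prediction(hm_all, cs$truth_infiltration, cs$edema_pre)
  ed <- cs$edema_pre$data[, , sl] > 0
  p <- mean(cs$truth_infiltration$data[, , sl][ed] > 0)
  expect_equal(ev3$voxel_accuracy, p)
  expect_equal(ev3$dice, 2 * p / (1 + p))
})

test_that("rendering is deterministic and sized by the working grid", {
  cs <- generate_phantom(quick_spec(seed = 2))
  sl <- select_slice(cs$tumor_pre, cs$edema_pre)
  hm <- tile_ratio_map(cs$adc_pre, cs$edema_pre, sl, tile_size = 2)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(hm, cs$adc_pre, f1)
  render_heatmap(hm, cs$adc_pre, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  px <- png::readPNG(f1)
  expect_equal(dim(px)[1:2], rev(dim(cs$adc_pre$data)[1:2]))

  m <- heatmap_mask(hm)
  expect_s3_class(m, "mask_volume")
  expect_equal(sum(m$data[, , sl] != (hm$predicted_mask + 0)), 0)
  expect_equal(sum(m$data) , sum(hm$predicted_mask))
})
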