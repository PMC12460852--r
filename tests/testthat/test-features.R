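mk_roi <- function(vals) {
  n <- length(vals)
  v <- volume_image(array(c(vals, rep(0, 2 * n)), c(n, 3, 1)))
  m <- mask_volume(array(c(rep(1, n), rep(0, 2 * n)), c(n, 3, 1)))
  list(v = v, m = m)
}

test_that("hand-checked examples: constant ROI and small integer ROI", {
  roi <- mk_roi(c(2, 2, 2, 2))
  f <- extract_features(roi$v, roi$m)
  expect_equal(f$meanADC, 2)
  expect_equal(f$stdmeanADC, 0)
  expect_identical(f$ratio_maxi_mean, 1)       # exactly 1 on constants
  expect_true(is.na(f$skewnessADC))            # m2 = 0: missing, not 0
  expect_true(is.na(f$kurtosisADC))

  roi <- mk_roi(c(1, 2, 3, 6))
  f <- extract_features(roi$v, roi$m)
  expect_equal(f$meanADC, 3)
  expect_equal(f$maxiADC, 6)
  expect_equal(f$miniADC, 1)
  expect_equal(f$medianADC, 2.5)               # mean of middle order stats
  expect_equal(f$ratio_maxi_mean, 2)
})

test_that("feature ordering invariants hold on random ROIs", {
  set.seed(10)
  for (i in 1:20) {
    roi <- mk_roi(rnorm(50, 1500, 200))
    f <- extract_features(roi$v, roi$m)
    expect_lte(f$miniADC, f$medianADC)
    expect_lte(f$medianADC, f$maxiADC)
    expect_gte(f$ratio_maxi_mean, 1)
    expect_gte(f$stdmeanADC, 0)
  }
})

test_that("moments of a large seeded normal sample match theory", {
  set.seed(77)
  roi <- mk_roi(rnorm(10000, 1500, 150))
  f <- extract_features(roi$v, roi$m)
  expect_lt(abs(f$skewnessADC), 0.08)
  expect_lt(abs(f$kurtosisADC - 3), 0.15)
  fe <- extract_features(roi$v, roi$m, excess_kurtosis = TRUE)
  expect_equal(fe$kurtosisADC, f$kurtosisADC - 3)
})

test_that("agreement with the naive loop oracle on 100 random ROIs (<= 1e-10 relative)", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    vals <- rnorm(n, runif(1, 500, 2500), runif(1, 10, 400))
    f <- extract_features(mk_roi(vals)$v, mk_roi(vals)$m)
    o <- naive_features(vals)
    for (nm in adc_feature_names()) {
      expect_lt(abs(f[[nm]] - o[[nm]]) / max(abs(o[[nm]]), 1), 1e-10)
    }
  }
})

test_that("affine intensity shift transforms the features predictably", {
  set.seed(9)
  vals <- rnorm(40, 1200, 180)
  c0 <- 250
  f <- extract_features(mk_roi(vals)$v, mk_roi(vals)$m)
  g <- extract_features(mk_roi(vals + c0)$v, mk_roi(vals + c0)$m)
  expect_equal(g$meanADC, f$meanADC + c0)
  expect_equal(g$medianADC, f$medianADC + c0)
  expect_equal(g$maxiADC, f$maxiADC + c0)
  expect_equal(g$miniADC, f$miniADC + c0)
  expect_equal(g$stdmeanADC, f$stdmeanADC)
  expect_equal(g$skewnessADC, f$skewnessADC)
  expect_equal(g$kurtosisADC, f$kurtosisADC)
  expect_equal(g$ratio_maxi_mean,
               (f$maxiADC + c0) / (f$meanADC + c0))
})

test_that("degenerate inputs raise the documented errors", {
  v <- volume_image(array(1, c(4, 1, 1)))
  empty <- mask_volume(array(0, c(4, 1, 1)))
  expect_error(extract_features(v, empty), "no voxels")
  one <- mask_volume(array(c(1, 0, 0, 0), c(4, 1, 1)))
  expect_error(extract_features(v, one), "fewer than 2")
  vna <- volume_image(array(c(NA, 1, 2, 3), c(4, 1, 1)))
  full <- mask_volume(array(1, c(4, 1, 1)))
  expect_error(extract_features(vna, full), "finite")
})

test_that("cohort feature table pairs rows and skips non-overlapping cases", {
  co <- generate_cohort(3, quick_spec(), seed = 17)
  tab <- cohort_feature_table(co)
  expect_equal(nrow(tab), 6)
  expect_equal(as.integer(table(tab$label)[c("no_rec", "rec")]), c(3L, 3L))
  expect_true(all(adc_feature_names() %in% names(tab)))
  # every case contributes exactly one row per label
  expect_true(all(table(tab$case_id, tab$label) == 1))
})
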