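test_that("phantom spec validation rejects bad parameters and geometry", {
  expect_error(phantom_spec(adc_edema_mean = -1), "means")
  expect_error(phantom_spec(adc_tumor_sd = -5), "sds")
  expect_error(phantom_spec(infil_angular_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(infil_outlier_fraction = 1), "fractions")
  expect_error(phantom_spec(infil_outlier_scale = 0), "scale")
  # lesion larger than the grid is rejected with an explicit message
  expect_error(generate_phantom(quick_spec(tumor_radius_mm = 30)),
               "does not fit")
})

test_that("identical (spec, seed) pairs give bit-identical phantoms", {
  a <- generate_phantom(quick_spec(seed = 7))
  b <- generate_phantom(quick_spec(seed = 7))
  expect_identical(a$adc_pre$data, b$adc_pre$data)
  expect_identical(a$adc_post$data, b$adc_post$data)
  expect_identical(a$truth_infiltration$data, b$truth_infiltration$data)
  c <- generate_phantom(quick_spec(seed = 8))
  expect_false(identical(a$adc_pre$data, c$adc_pre$data))
})

test_that("degenerate geometry: zero angular fraction gives empty infiltration", {
  cs <- generate_phantom(quick_spec(seed = 1, infil_angular_fraction = 0))
  expect_equal(sum(cs$truth_infiltration$data), 0)
  # edema then has a single mixture composition: base + free-water values
  vals <- cs$adc_pre$data[cs$edema_pre$data > 0]
  expect_true(all(vals > 0))
})

test_that("noiseless phantom intensities are exactly the component means", {
  cs <- generate_phantom(quick_spec(
    seed = 3, adc_background_sd = 0, adc_tumor_sd = 0, adc_edema_sd = 0,
    adc_infil_sd = 0, edema_freewater_fraction = 0,
    infil_outlier_fraction = 0))
  ed <- cs$adc_pre$data[cs$edema_pre$data > 0 & cs$truth_infiltration$data == 0]
  inf <- cs$adc_pre$data[cs$truth_infiltration$data > 0]
  expect_true(all(ed == 1500))
  expect_true(all(inf == 1250))
  expect_true(all(cs$adc_pre$data[cs$tumor_pre$data > 0] == 600))
})

test_that("structural invariants: disjointness and exact partition of edema", {
  cs <- generate_phantom(quick_spec(seed = 5))
  expect_equal(sum(cs$tumor_pre$data * cs$edema_pre$data), 0)
  expect_true(all(cs$truth_infiltration$data <= cs$edema_pre$data))
  complement <- cs$edema_pre$data - cs$truth_infiltration$data
  expect_true(all(complement %in% c(0, 1)))
  expect_equal(sum(cs$truth_infiltration$data) + sum(complement),
               sum(cs$edema_pre$data))
})

test_that("shell mean converges to the base edema component (seeded)", {
  cs <- generate_phantom(quick_spec(seed = 21, edema_freewater_fraction = 0))
  shell <- cs$adc_pre$data[cs$edema_pre$data > 0 &
                             cs$truth_infiltration$data == 0]
  n <- length(shell)
  expect_lt(abs(mean(shell) - 1500), 3 * 150 / sqrt(n))
})

test_that("inverse misalignment recovers the infiltration (dice >= 0.9)", {
  for (seed in c(2, 9)) {
    cs <- generate_phantom(quick_spec(seed = seed))
    back <- transform_mask(cs$tumor_rec_native, invert_rigid(cs$misalignment),
                           vol_grid(cs$edema_pre))
    inter <- mask_volume(back$data * cs$edema_pre$data, back$spacing,
                         back$origin, back$direction)
    expect_gte(dice_coefficient(inter, cs$truth_infiltration), 0.9)
  }
})

test_that("ROI-level max/mean ratio direction follows effect_direction on noiseless phantoms", {
  noiseless <- function(seed, dir) {
    generate_phantom(quick_spec(seed = seed, adc_background_sd = 0,
                                adc_tumor_sd = 0, adc_edema_sd = 0,
                                adc_infil_sd = 0, effect_direction = dir,
                                wedge_rotation_deg = seed * 7 %% 360))
  }
  ratio_pair <- function(cs) {
    comp <- mask_volume(cs$edema_pre$data - cs$truth_infiltration$data,
                        cs$edema_pre$spacing, cs$edema_pre$origin,
                        cs$edema_pre$direction)
    c(inf = extract_features(cs$adc_pre, cs$truth_infiltration)$ratio_maxi_mean,
      comp = extract_features(cs$adc_pre, comp)$ratio_maxi_mean)
  }
  lower <- vapply(1:50, function(s) {
    r <- ratio_pair(noiseless(s, "rec_lower_ratio"))
    r["inf"] < r["comp"]
  }, NA)
  expect_gte(sum(lower), 45)

  r <- ratio_pair(noiseless(4, "rec_higher_ratio"))
  expect_gt(r[["inf"]], r[["comp"]])
})

test_that("cohort generation is deterministic and respects its contract", {
  co <- generate_cohort(5, quick_spec(), seed = 31)
  expect_length(co, 5)
  co2 <- generate_cohort(5, quick_spec(), seed = 31)
  expect_identical(co[[3]]$adc_pre$data, co2[[3]]$adc_pre$data)
  for (cs in co) {
    expect_equal(sum(cs$tumor_pre$data * cs$edema_pre$data), 0)
    expect_true(all(cs$truth_infiltration$data <= cs$edema_pre$data))
  }
  expect_length(generate_cohort(1, quick_spec(), seed = 1), 1)
  expect_error(generate_cohort(0, quick_spec(), seed = 1))
})

test_that("phantom spec serializes to JSON and back", {
  sp <- quick_spec(seed = 12, infil_angular_fraction = 0.4,
                   misalignment = rigid_from_euler(c(0, 0, 2), c(1, 0, 0),
                                                   center = c(31, 31, 15)))
  f <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(sp, f)
  rd <- read_phantom_spec(f)
  expect_equal(rd$adc_edema_mean, sp$adc_edema_mean)
  expect_equal(rd$infil_angular_fraction, 0.4)
  expect_equal(rd$misalignment$rotation, sp$misalignment$rotation,
               tolerance = 1e-12)
  expect_identical(generate_phantom(rd)$adc_pre$data,
                   generate_phantom(sp)$adc_pre$data)
})
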