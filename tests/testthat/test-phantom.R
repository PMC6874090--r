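test_that("phantom specs are validated", {
  expect_error(small_phantom_spec(grid_shape = c(8, 40, 40)), ">= 16")
  expect_error(small_phantom_spec(baseline_fa = 0.1, delta_fa = 0.2),
               "baseline_fa - delta_fa")
  # lesion crossing the midsagittal plane is rejected with a clear message
  expect_error(small_phantom_spec(lesion_center_mm = c(4, 10, 0),
                                  lesion_radii_mm = c(8, 8, 8)),
               "straddles the midsagittal plane")
})

test_that("lesion effect profile: flat inside, exponential outside", {
  expect_equal(lesion_effect_profile(-5, 0.2, 10), 0.2)
  expect_equal(lesion_effect_profile(0, 0.2, 10), 0.2)
  # one decay length outside: delta / e, checked against exp directly
  expect_equal(lesion_effect_profile(10, 0.2, 10), 0.2 * exp(-1))
  d <- seq(0, 40, by = 0.5)
  eff <- lesion_effect_profile(d, 0.2, 8)
  expect_true(all(diff(eff) <= 0)) # monotone non-increasing outside
  expect_error(lesion_effect_profile(1, 0.2, 0), "> 0")
})

test_that("noise-free phantom maps equal baseline plus the injected effect", {
  spec0 <- small_phantom_spec(noise_sd_fa = 0, noise_sd_md = 0,
                              delta_fa = 0, delta_md = 0)
  ph0 <- generate_phantom(spec0)
  bundle <- Reduce(`|`, lapply(ph0$bundle_masks, function(m) m$data != 0))
  expect_true(all(ph0$fa$data[bundle] == spec0$baseline_fa))
  expect_true(all(ph0$fa$data[!bundle] == 0))
  expect_equal(max(abs(ph0$md$data - spec0$baseline_md)), 0)

  # lesion centered on the right bundle centerline: center voxel carries the
  # full FA decrement, and the in-lesion bundle mean equals
  # baseline - delta exactly
  y0 <- 15
  z0 <- 18 - (y0 / 30)^2 * 28
  spec1 <- small_phantom_spec(noise_sd_fa = 0, noise_sd_md = 0,
                              delta_fa = 0.2,
                              lesion_center_mm = c(18, y0, z0),
                              lesion_radii_mm = c(7, 8, 7))
  ph1 <- generate_phantom(spec1)
  ctr <- world_to_voxel(matrix(spec1$lesion_center_mm, 1), ph1$fa)
  expect_equal(ph1$fa$data[ctr], spec1$baseline_fa - 0.2)
  bundle1 <- Reduce(`|`, lapply(ph1$bundle_masks, function(m) m$data != 0))
  interior <- bundle1 & ph1$lesion_mask$data != 0
  expect_equal(mean(ph1$fa$data[interior]), spec1$baseline_fa - 0.2,
               tolerance = 1e-12)
})

test_that("phantom generation is deterministic and lesion is unilateral", {
  spec <- small_phantom_spec()
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$fa$data, b$fa$data)
  expect_identical(a$md$data, b$md$data)
  expect_identical(a$direction_field, b$direction_field)

  # hemisphere masks partition the grid and cover all bundle voxels
  lh <- a$left_hemisphere_mask$data
  rh <- a$right_hemisphere_mask$data
  expect_true(all(lh + rh == 1))
  for (m in a$bundle_masks) {
    expect_true(all(lh[m$data != 0] + rh[m$data != 0] == 1))
  }
  expect_true(all(a$lesion_mask$data[lh == 1] == 0)) # right-sided lesion

  # unit-norm directions wherever FA > 0
  nz <- which(a$fa$data > 0)
  npx <- prod(dim(a$fa$data))
  nrm <- sqrt(a$direction_field[nz]^2 + a$direction_field[nz + npx]^2 +
                a$direction_field[nz + 2 * npx]^2)
  expect_equal(range(nrm), c(1, 1), tolerance = 1e-12)
})

test_that("contralesional data do not depend on lesion effect sizes", {
  base <- small_phantom_spec()
  more <- small_phantom_spec(delta_fa = 0.05, delta_md = 1e-4)
  a <- generate_phantom(base)
  b <- generate_phantom(more)
  contra <- a$left_hemisphere_mask$data == 1
  expect_identical(a$fa$data[contra], b$fa$data[contra])
  expect_identical(a$md$data[contra], b$md$data[contra])
})

test_that("phantoms round-trip through NIfTI + JSON", {
  ph <- generate_phantom(small_phantom_spec())
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_phantom(dir)
  expect_lt(max(abs(back$fa$data - ph$fa$data)), 1e-6)
  expect_identical(back$lesion_mask$data, ph$lesion_mask$data)
  expect_equal(back$fa$affine, ph$fa$affine, tolerance = 1e-5)
  expect_equal(dim(back$direction_field), dim(ph$direction_field))
  expect_equal(back$truth$lesion_volume_cm3, ph$truth$lesion_volume_cm3)
})

test_that("cohorts are unilateral, varied and reproducible", {
  cohort <- phantom_cohort(6, base_spec = small_phantom_spec(), rng_seed = 3)
  cohort2 <- phantom_cohort(6, base_spec = small_phantom_spec(), rng_seed = 3)
  expect_identical(cohort, cohort2)
  sides <- vapply(cohort, function(s) sign(s$lesion_center_mm[1]),
                  numeric(1))
  expect_true(any(sides > 0) && any(sides < 0)) # lesions on both sides
  radii <- vapply(cohort, function(s) s$lesion_radii_mm[1], numeric(1))
  expect_gt(stats::sd(radii), 0) # sizes vary across subjects
})
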