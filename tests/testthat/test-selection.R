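test_that("streamline-mask intersection detects thin crossings", {
  dm <- c(20, 20, 20)
  inside_mask <- box_mask(dm, c(5, 5, 5), c(15, 15, 15))
  sl_in <- cbind(seq(6, 12, by = 0.5), 10, 10) # fully inside
  sl_out <- cbind(seq(0, 3, by = 0.5), 1, 1) # fully outside
  expect_true(streamline_intersects(sl_in, inside_mask))
  expect_false(streamline_intersects(sl_out, inside_mask))

  # one-voxel-thick wall crossed by a segment whose endpoints are far apart:
  # densification must still catch the crossing
  wall <- box_mask(dm, c(10, 1, 1), c(10, 20, 20))
  crossing <- rbind(c(2, 10, 10), c(18, 10, 10)) # 16-mm jump over the wall
  expect_true(streamline_intersects(crossing, wall))
  # brute-force oracle: dense points along the segment
  t <- seq(0, 1, length.out = 2000)
  dense <- cbind(2 + 16 * t, 10, 10)
  oracle <- any(sample_map(dense, wall, "nearest") > 0, na.rm = TRUE)
  expect_identical(streamline_intersects(crossing, wall), oracle)
})

test_that("recipes validate and select with ROI-AND / ROA-NONE semantics", {
  dm <- c(20, 20, 20)
  roi <- box_mask(dm, c(1, 1, 1), c(20, 20, 20))
  sub <- box_mask(dm, c(5, 5, 5), c(10, 10, 10))
  expect_error(selection_recipe("bad", sub, roi), "fully inside")

  set.seed(30)
  pts <- lapply(1:12, function(i) {
    start <- runif(3, 2, 16)
    rbind(start, start + c(3, 0.5, 0.5))
  })
  s <- streamline_set(pts)
  all_grid <- selection_recipe("all", roi)
  expect_equal(n_streamlines(select_streamlines(s, all_grid)), 12)
  # an ROA covering every streamline selects nothing (the recipe is still
  # valid because part of the ROI lies outside the ROA)
  roa_most <- box_mask(dm, c(1, 1, 1), c(20, 20, 18))
  expect_warning(
    empty <- select_streamlines(
      s, selection_recipe("empty", roi, roa_most)
    ),
    "no streamlines"
  )
  expect_equal(n_streamlines(empty), 0)
})

test_that("IE and II partition I on the phantom", {
  ph <- generate_phantom(small_phantom_spec())
  seed_mask <- mask_volume(array(1, dim(ph$fa$data)), ph$fa$affine)
  tr <- track(ph$direction_field, ph$fa, seed_mask,
              tracking_params(n_seeds = 3000, rng_seed = 5))
  bundle <- ph$bundle_masks$right_2
  contra <- ph$left_hemisphere_mask
  lesion <- ph$lesion_mask
  sel_i <- select_streamlines(tr, selection_recipe("I", bundle, contra))
  sel_ie <- select_streamlines(
    tr, selection_recipe("IE", bundle, list(contra, lesion))
  )
  sel_ii <- select_streamlines(
    tr, selection_recipe("II", list(bundle, lesion), contra)
  )
  expect_equal(n_streamlines(sel_ie) + n_streamlines(sel_ii),
               n_streamlines(sel_i))
  expect_gt(n_streamlines(sel_ie), 0)
  expect_gt(n_streamlines(sel_ii), 0)
  # selection is idempotent
  again <- select_streamlines(sel_i, selection_recipe("I", bundle, contra))
  expect_equal(n_streamlines(again), n_streamlines(sel_i))
})

test_that("tract-value extraction collects visited-voxel values", {
  dm <- c(20, 5, 5)
  dat <- array(0, dm)
  dat[, 3, 3] <- seq_len(20) # known values along one row
  vol <- scalar_volume(dat, diag(4))
  sl <- cbind(seq(2, 17, by = 1), 2, 2) # along the (zero-based) row y=z=2
  s <- streamline_set(list(sl))
  got <- extract_tract_values(s, vol)
  expect_setequal(got$value, 3:18)

  const <- scalar_volume(array(4, dm), diag(4))
  expect_true(all(extract_tract_values(s, const)$value == 4))

  # deduplication: a duplicated streamline adds nothing
  s2 <- streamline_set(list(sl, sl))
  expect_equal(sort(extract_tract_values(s2, vol)$value),
               sort(got$value))
  # per-visit mode counts both traversals
  twice <- extract_tract_values(s2, vol, dedupe = FALSE)
  expect_equal(nrow(twice), 2 * nrow(got))
})

test_that("min-max normalization spans [0, 1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(31)
  v <- rnorm(50)
  nv <- minmax_normalize(v)
  expect_equal(range(nv), c(0, 1))
  expect_equal(minmax_normalize(3 * v + 7), nv)
  expect_error(minmax_normalize(rep(1, 5)), "constant")
})
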