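test_that("volumes round-trip through NIfTI, anisotropic voxels preserved", {
  set.seed(10)
  # clinical-style anisotropic geometry: 0.47 x 0.47 x 2 mm
  aff <- diag(c(0.47, 0.47, 2, 1))
  aff[1:3, 4] <- c(-20, -25, -12)
  vol <- scalar_volume(array(runif(20 * 22 * 12), c(20, 22, 12)), aff)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$affine, vol$affine, tolerance = 1e-5)
  expect_equal(back$voxel_size_mm, c(0.47, 0.47, 2), tolerance = 1e-6)
  expect_lt(max(abs(back$data - vol$data)), 1e-6) # float32 storage

  m <- mask_volume(array(rbinom(20 * 22 * 12, 1, 0.3), c(20, 22, 12)), aff)
  mpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, mpath)
  mback <- read_volume(mpath, mask = TRUE)
  expect_identical(mback$data, m$data) # integer data round-trip exactly
})

test_that("degenerate affines are rejected", {
  bad <- diag(4)
  bad[1, 1] <- 0
  expect_error(scalar_volume(array(0, c(16, 16, 16)), bad),
               "not invertible")
  bad2 <- diag(4)
  bad2[4, ] <- c(1, 0, 0, 1)
  expect_error(scalar_volume(array(0, c(16, 16, 16)), bad2), "last affine")
})

test_that("world/voxel conversion uses the floor voxel-center convention", {
  vol <- scalar_volume(array(0, c(16, 16, 16)), diag(4))
  idx <- world_to_voxel(cbind(2.4, 0, 0), vol)
  # continuous coordinate 2.4 -> zero-based voxel 2 -> R index 3
  expect_equal(as.vector(idx), c(3, 1, 1))
  # mapping back gives the voxel center
  expect_equal(as.vector(voxel_to_world(idx, vol)), c(2, 0, 0))
})

test_that("coordinate round trips match a direct matrix solve", {
  set.seed(11)
  for (rep in 1:5) {
    aff <- diag(4)
    aff[1:3, 1:3] <- matrix(rnorm(9), 3, 3) + diag(3) * 2
    aff[1:3, 4] <- rnorm(3, sd = 5)
    vol <- scalar_volume(array(0, c(16, 16, 16)), aff)
    pts <- matrix(rnorm(600, sd = 4), ncol = 3)
    cont <- world_to_voxel(pts, vol, continuous = TRUE)
    # oracle: solve the 4x4 system directly per point
    oracle <- t(apply(pts, 1, function(p) {
      solve(aff, c(p, 1))[1:3]
    }))
    expect_equal(cont, oracle, tolerance = 1e-10)
    # center of each voxel maps back exactly
    idx <- world_to_voxel(pts, vol)
    expect_equal(
      world_to_voxel(voxel_to_world(idx, vol), vol, continuous = TRUE),
      idx - 1,
      tolerance = 1e-8, ignore_attr = TRUE
    )
  }
})

test_that("sampling: nearest and trilinear behave as specified", {
  vol <- scalar_volume(array(7, c(8, 8, 8)), diag(4))
  pts <- matrix(runif(30, 0.5, 6.5), ncol = 3)
  expect_equal(sample_map(pts, vol, "nearest"), rep(7, 10))
  expect_equal(sample_map(pts, vol, "trilinear"), rep(7, 10))

  dat <- array(0, c(8, 8, 8))
  dat[3, 4, 5] <- 2; dat[4, 4, 5] <- 6
  v2 <- scalar_volume(dat, diag(4))
  # voxel centers (zero-based 2,3,4) and (3,3,4)
  expect_equal(sample_map(cbind(2, 3, 4), v2, "nearest"), 2)
  expect_equal(sample_map(cbind(2, 3, 4), v2, "trilinear"), 2)
  # midpoint between the two centers along x: arithmetic mean
  expect_equal(sample_map(cbind(2.5, 3, 4), v2, "trilinear"), 4)
  # outside the grid is flagged
  expect_true(is.na(sample_map(cbind(40, 3, 4), v2, "nearest")))
})

test_that("sampling is invariant under a common rigid transform", {
  set.seed(12)
  vol <- scalar_volume(array(runif(16^3), c(16, 16, 16)), diag(4))
  pts <- matrix(runif(150, 2, 13), ncol = 3)
  for (rep in 1:3) {
    rig <- random_rigid()
    moved <- rigid_volume(vol, rig)
    for (mode in c("nearest", "trilinear")) {
      expect_equal(
        sample_map(apply_rigid(pts, rig), moved, mode),
        sample_map(pts, vol, mode),
        tolerance = 1e-8
      )
    }
  }
})
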