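test_that("common node count averages streamline point counts", {
  s50 <- streamline_set(lapply(1:4, function(i) cbind(seq_len(50), i, 0)))
  expect_equal(common_node_count(s50), 50)
  s40 <- streamline_set(list(cbind(seq_len(40), 0, 0)))
  s60 <- streamline_set(list(cbind(seq_len(60), 0, 0)))
  expect_equal(common_node_count(s40, s60), 50)
  set.seed(60)
  counts <- sample(10:90, 7)
  sets <- lapply(counts, function(n) {
    streamline_set(list(cbind(seq_len(n), 0, 0)))
  })
  expect_equal(do.call(common_node_count, sets),
               max(2L, round(mean(counts))))
})

test_that("resampling preserves geometry", {
  # straight segment: equally spaced collinear nodes
  seg <- resample_streamline(rbind(c(0, 0, 0), c(9, 0, 0)), 10)
  expect_equal(seg[, 1], 0:9)
  expect_true(all(seg[, 2:3] == 0))

  # near-identity on an already-uniform polyline (uniform chord lengths)
  th <- seq(0, pi / 3, length.out = 21)
  p <- cbind(30 * cos(th), 30 * sin(th), 0)
  r <- resample_streamline(p, nrow(p))
  expect_lt(max(abs(r - p)), 0.01 * sqrt(sum((p[2, ] - p[1, ])^2)))

  # quarter circle, radius 10: arc length 5*pi recovered within 0.1%,
  # spacing uniform within 1%
  theta <- seq(0, pi / 2, length.out = 30)
  arc <- cbind(10 * cos(theta), 10 * sin(theta), 0)
  rr <- resample_streamline(arc, 100)
  len <- arc_length(rr)
  expect_lt(abs(len - 5 * pi) / (5 * pi), 0.001)
  spac <- sqrt(rowSums(diff(rr)^2))
  expect_lt(max(abs(spac - mean(spac))) / mean(spac), 0.01)
  # endpoints preserved exactly
  expect_equal(rr[1, ], arc[1, ])
  expect_equal(rr[100, ], arc[30, ])
})

test_that("resampling is equivariant under rigid transforms", {
  set.seed(61)
  t <- seq(0, 1, length.out = 25)
  p <- cbind(30 * t, 10 * sin(2 * t), 5 * t^2)
  for (rep in 1:3) {
    rig <- random_rigid()
    a <- apply_rigid(resample_streamline(p, 40), rig)
    b <- resample_streamline(apply_rigid(p, rig), 40)
    expect_equal(a, b, tolerance = 1e-8)
  }
  # arc length is monotone along the resampled nodes by construction
  r <- resample_streamline(p, 40)
  expect_true(all(sqrt(rowSums(diff(r)^2)) > 0))
})

test_that("normalization to the contralesional mean", {
  expect_equal(normalize_to_contralesional(c(2, 2), 2), c(1, 1))
  v <- c(1, 2, 3)
  expect_equal(normalize_to_contralesional(2 * v, 2 * 2),
               normalize_to_contralesional(v, 2))
  expect_equal(mean(normalize_to_contralesional(v, mean(v))), 1)
  expect_error(normalize_to_contralesional(v, 0), "> 0")
})

test_that("signed distances match sphere geometry and a brute-force oracle", {
  aff <- diag(4)
  dm <- c(41, 41, 41)
  ctr <- c(20, 20, 20) # world coords of the central voxel
  g <- expand.grid(x = 0:40, y = 0:40, z = 0:40)
  inside <- sqrt((g$x - 20)^2 + (g$y - 20)^2 + (g$z - 20)^2) <= 10
  sphere <- mask_volume(array(as.numeric(inside), dm), aff)
  d_ctr <- signed_distance(matrix(ctr, 1), sphere)
  expect_lt(abs(d_ctr - (-10)), 1) # within one voxel of -radius
  d_out <- signed_distance(matrix(c(40, 20, 20), 1), sphere)
  expect_lt(abs(d_out - 10), 1)

  # anisotropic random blob vs exhaustive boundary search
  aff2 <- diag(c(1, 1.3, 2, 1))
  dm2 <- c(24, 20, 14)
  set.seed(62)
  blob <- array(0, dm2)
  blob[7:17, 6:15, 4:10] <- rbinom(11 * 10 * 7, 1, 0.8)
  mask <- mask_volume(blob, aff2)
  pts <- cbind(runif(300, 0, 23), runif(300, 0, 19 * 1.3),
               runif(300, 0, 13 * 2))
  got <- signed_distance(pts, mask)
  # oracle: plain double loop over all boundary voxel centers
  bnd <- which(mask$data != 0, arr.ind = TRUE)
  is_boundary <- apply(bnd, 1, function(v) {
    for (ax in 1:3) for (dd in c(-1, 1)) {
      w <- v; w[ax] <- w[ax] + dd
      if (any(w < 1) || any(w > dm2)) return(TRUE)
      if (mask$data[w[1], w[2], w[3]] == 0) return(TRUE)
    }
    FALSE
  })
  bw <- voxel_to_world(bnd[is_boundary, , drop = FALSE], mask)
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    dmin <- min(sqrt(colSums((t(bw) - pts[i, ])^2)))
    inside_i <- sample_map(pts[i, , drop = FALSE], mask, "nearest")
    if (!is.na(inside_i) && inside_i > 0) -dmin else dmin
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("lesion flip is a volume-preserving involution", {
  set.seed(63)
  dm <- c(30, 26, 22)
  m <- array(0, dm)
  m[19:27, 5:12, 8:14] <- rbinom(9 * 8 * 7, 1, 0.6) # right-sided blob
  mask <- mask_volume(m, diag(c(2, 2, 2, 1)))
  fl <- flip_lesion(mask, 1)
  expect_identical(flip_lesion(fl, 1)$data, mask$data)
  expect_equal(sum(fl$data), sum(mask$data))
  # centroid is reflected about the grid center plane
  cm <- colMeans(which(mask$data != 0, arr.ind = TRUE))
  cf <- colMeans(which(fl$data != 0, arr.ind = TRUE))
  expect_equal(cf[1], dm[1] + 1 - cm[1])
  expect_equal(cf[2:3], cm[2:3])
  expect_warning(flip_lesion(mask_volume(array(1, dm), diag(4)), 1),
                 "straddles")
})

test_that("binned profiles summarize with t confidence intervals", {
  prof <- tibble::tibble(
    distance_mm = c(-3, -1, 1, 3, 1.5, 2.5),
    value = c(5, 5, 5, 5, 5, 5),
    group = "A"
  )
  bp <- binned_profile(prof, bin_width_mm = 2)
  expect_true(all(bp$mean == 5))
  expect_true(all(bp$ci_low == 5 & bp$ci_high == 5)) # zero-width CIs
  expect_equal(sum(bp$n), 6)

  set.seed(64)
  vals <- rnorm(40, mean = 2, sd = 0.5)
  prof2 <- tibble::tibble(distance_mm = rep(0.5, 40), value = vals,
                          group = "B")
  bp2 <- binned_profile(prof2, bin_width_mm = 2)
  expect_equal(nrow(bp2), 1) # everything in one bin
  expect_equal(bp2$n, 40)
  sem <- sd(vals) / sqrt(40)
  expect_equal(bp2$mean, mean(vals))
  expect_equal(bp2$ci_low, mean(vals) - qt(0.975, 39) * sem)
  expect_equal(bp2$ci_high, mean(vals) + qt(0.975, 39) * sem)
})

test_that("CI overlap flags use the closed-interval convention", {
  bp <- tibble::tibble(
    bin_center_mm = c(1, 1, 3, 3, 5, 5),
    group = rep(c("A", "B"), 3),
    mean = c(0.5, 0.5, 0.5, 2.5, 0.5, 1.5),
    ci_low = c(0, 0, 0, 2, 0, 1),
    ci_high = c(1, 1, 1, 3, 1, 2),
    n = 10, low_n = FALSE
  )
  flags <- ci_overlap_flags(bp, c("A", "B"))
  expect_equal(flags$nonoverlap, c(FALSE, TRUE, FALSE))
})
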