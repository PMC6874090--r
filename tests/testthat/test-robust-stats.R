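# independent brute-force Harrell-Davis oracle: beta weights by numerical
# integration of the beta density over each order-statistic cell
hd_oracle <- function(x, q) {
  n <- length(x)
  xs <- sort(x)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  w <- vapply(seq_len(n), function(i) {
    stats::integrate(function(t) stats::dbeta(t, a, b),
                     (i - 1) / n, i / n,
                     rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
  sum(w * xs)
}

test_that("Harrell-Davis estimator matches its defining beta weights", {
  expect_equal(harrell_davis(rep(3.5, 12), 0.25), 3.5) # weights sum to 1
  expect_equal(harrell_davis(1:9, 0.5), 5) # symmetry center
  expect_equal(harrell_davis(1:10, 0.3), hd_oracle(1:10, 0.3),
               tolerance = 1e-10)
  set.seed(40)
  for (rep in 1:10) {
    x <- rnorm(sample(10:60, 1))
    q <- runif(1, 0.05, 0.95)
    expect_equal(harrell_davis(x, q), hd_oracle(x, q), tolerance = 1e-10)
  }
})

test_that("Harrell-Davis is monotone, bounded, location-scale equivariant", {
  set.seed(41)
  q <- seq(0.1, 0.9, by = 0.1)
  for (rep in 1:10) {
    x <- rt(40, df = 3)
    est <- harrell_davis(x, q)
    expect_true(all(diff(est) >= 0))
    expect_gte(min(est), min(x))
    expect_lte(max(est), max(x))
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_equal(harrell_davis(a * x + b, q), a * est + b,
                 tolerance = 1e-12)
  }
})

test_that("shift function: identity, translation and swap behave correctly", {
  set.seed(42)
  x <- rnorm(300)
  sf_id <- shift_function(x, x, rng_seed = 1)
  expect_equal(sf_id$difference, rep(0, 9))
  expect_false(any(sf_id$significant))
  expect_true(all(sf_id$ci_low <= sf_id$difference &
                    sf_id$difference <= sf_id$ci_high))
  expect_true(all(diff(sf_id$est1) >= 0)) # deciles non-decreasing

  sf_shift <- shift_function(x, x + 2, rng_seed = 1)
  expect_equal(sf_shift$difference, rep(-2, 9), tolerance = 1e-12)
  expect_true(all(sf_shift$significant))

  sf_ab <- shift_function(x, x + 0.5, rng_seed = 2)
  sf_ba <- shift_function(x + 0.5, x, rng_seed = 2)
  expect_equal(sf_ab$difference, -sf_ba$difference, tolerance = 1e-12)

  # deterministic given the seed
  expect_equal(shift_function(x, x + 1, rng_seed = 9),
               shift_function(x, x + 1, rng_seed = 9))
  expect_warning(shift_function(rnorm(10), rnorm(30)), "fewer than 20")
})

test_that("phantom hemispheres produce the expected FA shift direction", {
  ph <- generate_phantom(small_phantom_spec())
  seed_mask <- mask_volume(array(1, dim(ph$fa$data)), ph$fa$affine)
  tr <- track(ph$direction_field, ph$fa, seed_mask,
              tracking_params(n_seeds = 4000, rng_seed = 11))
  ipsi <- select_streamlines(
    tr, selection_recipe("ipsi", ph$right_hemisphere_mask,
                         ph$left_hemisphere_mask)
  )
  contra <- select_streamlines(
    tr, selection_recipe("contra", ph$left_hemisphere_mask,
                         ph$right_hemisphere_mask)
  )
  fa_i <- extract_tract_values(ipsi, ph$fa)$value
  fa_c <- extract_tract_values(contra, ph$fa)$value
  sf <- shift_function(fa_i, fa_c, rng_seed = 3)
  # lesion lowers ipsilesional FA: upper deciles shift negative
  expect_true(all(sf$difference[sf$decile >= 0.5] < 0))
  expect_true(any(sf$significant))
})

test_that("downsampled Wilcoxon matches an independent implementation", {
  set.seed(43)
  x <- rnorm(500)
  res <- wilcoxon_downsampled(x, x, factor = 50, rng_seed = 5)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_equal(res$n1, 10)

  a <- rnorm(600, mean = 3) # well-separated
  b <- rnorm(600)
  res2 <- wilcoxon_downsampled(a, b, factor = 50, rng_seed = 5)
  expect_gt(res2$z, 0)
  res3 <- wilcoxon_downsampled(b, a, factor = 50, rng_seed = 5)
  expect_equal(res3$z, -res2$z) # antisymmetric in the arguments

  # oracle: stats::wilcox.test normal approximation on the same subsample
  set.seed(5) # reproduce the internal per-sample subsampling
  xs <- a[sample.int(length(a), 12)]
  set.seed(5)
  ys <- b[sample.int(length(b), 12)]
  ours <- wilcoxon_downsampled(a, b, factor = 50, rng_seed = 5)
  wt <- suppressWarnings(
    stats::wilcox.test(xs, ys, exact = FALSE, correct = FALSE)
  )
  expect_equal(ours$p, wt$p.value, tolerance = 1e-12)
  expect_error(wilcoxon_downsampled(rnorm(10), rnorm(600)), "at least")
})

test_that("mirrored densities integrate to one with correct medians", {
  set.seed(44)
  x <- rnorm(400); y <- rexp(300)
  md <- mirrored_density_summary(x, y)
  for (g in c("1", "2")) {
    d <- md[md$group == g, ]
    integral <- sum(diff(d$value) * (d$density[-1] + d$density[-nrow(d)]) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  expect_equal(attr(md, "medians"), c(median(x), median(y)))
})
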