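# Small-scale fixtures shared across test files. All data are generated in
# code; nothing is read from disk.

# a compact phantom spec: same structure as the default study phantom but a
# smaller grid and fewer truth streamlines, for fast unit tests
small_phantom_spec <- function(...) {
  y <- c(-30, -15, 0, 15, 30)
  z <- 18 - (y / 30)^2 * 28
  bundles <- list(
    bundle_spec(cbind(-18, y, z), radius_mm = 5,
                n_streamlines_truth = 20, hemisphere = "left"),
    bundle_spec(cbind(18, y, z), radius_mm = 5,
                n_streamlines_truth = 20, hemisphere = "right")
  )
  defaults <- list(
    grid_shape = c(40, 48, 40),
    voxel_size_mm = c(2, 2, 2),
    bundles = bundles,
    lesion_center_mm = c(26, 15, 8),
    lesion_radii_mm = c(8, 9, 8)
  )
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# an axis-aligned box mask on a given grid
box_mask <- function(dim3, lo, hi, affine = diag(4)) {
  a <- array(0, dim3)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  mask_volume(a, affine)
}

# a random rigid transform (rotation + translation)
random_rigid <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  rot <- qr.Q(qr_d)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(points, rigid) {
  t(rigid$rot %*% t(points) + rigid$shift)
}

rigid_volume <- function(volume, rigid) {
  aff <- volume$affine
  aff[1:3, 1:3] <- rigid$rot %*% aff[1:3, 1:3]
  aff[1:3, 4] <- rigid$rot %*% aff[1:3, 4] + rigid$shift
  out <- scalar_volume(volume$data, aff)
  if (inherits(volume, "mask_volume")) class(out) <-
      c("mask_volume", class(out))
  out
}
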