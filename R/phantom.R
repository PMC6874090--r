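#' Bundle specification for the synthetic phantom
#'
#' Describes one arched white-matter bundle as a tube of circular cross
#' section around a smooth centerline (an analog of the corticospinal tract
#' or superior longitudinal fasciculus). The centerline is interpolated
#' through the control points with a cubic spline parameterized by arc
#' length.
#'
#' @param centerline_control_points_mm ordered m x 3 matrix of world points
#'   (m >= 3).
#' @param radius_mm tube radius in mm (> 0).
#' @param n_streamlines_truth number of ground-truth streamlines generated
#'   inside the tube.
#' @param hemisphere `"left"` or `"right"`.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(centerline_control_points_mm, radius_mm = 6,
                        n_streamlines_truth = 100,
                        hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  cp <- as_points_matrix(centerline_control_points_mm)
  if (nrow(cp) < 3) stop("need >= 3 centerline control points", call. = FALSE)
  if (radius_mm <= 0) stop("radius_mm must be > 0", call. = FALSE)
  structure(
    list(
      centerline_control_points_mm = cp,
      radius_mm = radius_mm,
      n_streamlines_truth = as.integer(n_streamlines_truth),
      hemisphere = hemisphere
    ),
    class = "bundle_spec"
  )
}

default_phantom_bundles <- function(radius_mm = 8, n_streamlines_truth = 100) {
  # arched CST-like bundle in the y-z plane at fixed |x|; mirror pair
  y <- c(-48, -24, 0, 24, 48)
  z <- 30 - (y / 48)^2 * 45
  right <- cbind(28, y, z)
  left <- cbind(-28, y, z)
  list(
    bundle_spec(left, radius_mm, n_streamlines_truth, "left"),
    bundle_spec(right, radius_mm, n_streamlines_truth, "right")
  )
}

#' Phantom specification
#'
#' Parameters of the synthetic two-hemisphere diffusion phantom: grid
#' geometry, arched fiber bundles, an ellipsoidal lesion confined to one
#' hemisphere, the diffusion effect injected around it, and measurement
#' noise. The injected effect lowers FA and raises MD/AD/RD at full strength
#' inside the lesion and decays exponentially with distance outside it (see
#' [lesion_effect_profile()]).
#'
#' Noise is additive Gaussian, specified separately for FA (unitless scale)
#' and for the diffusivities (mm^2/s scale), drawn from per-hemisphere,
#' per-map substreams so contralesional data do not depend on lesion
#' parameters. Defaults give an effect-to-noise ratio of 5 for both FA and
#' MD.
#'
#' @param grid_shape voxels per axis (all >= 16).
#' @param voxel_size_mm per-axis spacing in mm.
#' @param midsagittal_axis axis index (1-3) of the hemisphere-separating
#'   plane; the plane passes through the grid center.
#' @param bundles list of [bundle_spec()] objects.
#' @param lesion_center_mm,lesion_radii_mm ellipsoid center (world mm) and
#'   semi-axes (mm).
#' @param delta_fa FA decrement at full effect (unitless).
#' @param delta_md MD increment at full effect (mm^2/s).
#' @param effect_decay_mm e-folding length of the effect outside the lesion.
#' @param baseline_fa,baseline_md,baseline_ad,baseline_rd healthy-tissue
#'   values.
#' @param ad_scale,rd_scale AD/RD effect sizes as multiples of the MD effect.
#' @param noise_sd_fa,noise_sd_md additive Gaussian noise sd for FA and for
#'   the diffusivity maps.
#' @param hemisphere_asymmetry relative right-minus-left difference in the
#'   healthy baselines (all maps): right baselines are scaled by
#'   `1 + a/2`, left by `1 - a/2`. Default 0; [phantom_cohort()] draws a
#'   small value per subject to emulate physiological hemispheric
#'   asymmetry.
#' @param rng_seed integer seed controlling all phantom randomness.
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec()
#' spec$lesion_center_mm
#' @export
phantom_spec <- function(grid_shape = c(60, 72, 60),
                         voxel_size_mm = c(2, 2, 2),
                         midsagittal_axis = 1,
                         bundles = default_phantom_bundles(),
                         lesion_center_mm = c(40, 24, 19),
                         lesion_radii_mm = c(12, 14, 12),
                         delta_fa = 0.2,
                         delta_md = 3e-4,
                         effect_decay_mm = 2,
                         baseline_fa = 0.7,
                         baseline_md = 8e-4,
                         baseline_ad = 1.4e-3,
                         baseline_rd = 5e-4,
                         ad_scale = 1,
                         rd_scale = 1,
                         noise_sd_fa = 0.04,
                         noise_sd_md = 6e-5,
                         hemisphere_asymmetry = 0,
                         rng_seed = 42L) {
  spec <- list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    midsagittal_axis = as.integer(midsagittal_axis),
    bundles = bundles,
    lesion_center_mm = as.numeric(lesion_center_mm),
    lesion_radii_mm = as.numeric(lesion_radii_mm),
    delta_fa = delta_fa, delta_md = delta_md,
    effect_decay_mm = effect_decay_mm,
    baseline_fa = baseline_fa, baseline_md = baseline_md,
    baseline_ad = baseline_ad, baseline_rd = baseline_rd,
    ad_scale = ad_scale, rd_scale = rd_scale,
    noise_sd_fa = noise_sd_fa, noise_sd_md = noise_sd_md,
    hemisphere_asymmetry = hemisphere_asymmetry,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 16)) {
    stop("grid_shape entries must all be >= 16", call. = FALSE)
  }
  if (any(spec$voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be > 0", call. = FALSE)
  }
  if (!(spec$baseline_fa > 0 && spec$baseline_fa <= 1)) {
    stop("need 0 < baseline_fa <= 1", call. = FALSE)
  }
  if (spec$baseline_fa - spec$delta_fa < 0) {
    stop("baseline_fa - delta_fa must be >= 0", call. = FALSE)
  }
  if (spec$effect_decay_mm <= 0) {
    stop("effect_decay_mm must be > 0", call. = FALSE)
  }
  if (!spec$midsagittal_axis %in% 1:3) {
    stop("midsagittal_axis must be 1, 2 or 3", call. = FALSE)
  }
  ax <- spec$midsagittal_axis
  c_ax <- spec$lesion_center_mm[ax]
  r_ax <- spec$lesion_radii_mm[ax]
  # grid is world-centered, so the midsagittal plane is coordinate 0 on ax
  if (abs(c_ax) - r_ax <= 0) {
    stop("lesion ellipsoid straddles the midsagittal plane; ",
         "it must lie entirely within one hemisphere", call. = FALSE)
  }
  invisible(spec)
}

#' Lesion effect as a function of distance
#'
#' Full effect `delta` inside the lesion (signed distance <= 0), exponential
#' decay `delta * exp(-distance / effect_decay_mm)` outside; continuous at
#' the boundary.
#'
#' @param distance_mm signed distance to the lesion boundary (negative
#'   inside).
#' @param delta effect size at and inside the boundary.
#' @param effect_decay_mm e-folding length (> 0) of the decay outside.
#' @return effect values, same length as `distance_mm`.
#' @examples
#' lesion_effect_profile(c(-5, 0, 10), 0.2, 10)
#' @export
lesion_effect_profile <- function(distance_mm, delta, effect_decay_mm) {
  if (effect_decay_mm <= 0) stop("effect_decay_mm must be > 0", call. = FALSE)
  ifelse(distance_mm <= 0, delta,
         delta * exp(-distance_mm / effect_decay_mm))
}

phantom_affine <- function(spec) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(spec$voxel_size_mm)
  aff[1:3, 4] <- -spec$voxel_size_mm * (spec$grid_shape - 1) / 2
  aff
}

# world coordinates of all voxel centers, one column per axis
voxel_center_grid <- function(spec) {
  aff <- phantom_affine(spec)
  ax <- lapply(1:3, function(a) {
    (seq_len(spec$grid_shape[a]) - 1) * spec$voxel_size_mm[a] + aff[a, 4]
  })
  dm <- spec$grid_shape
  list(
    x = array(rep(ax[[1]], times = dm[2] * dm[3]), dm),
    y = array(rep(rep(ax[[2]], each = dm[1]), times = dm[3]), dm),
    z = array(rep(ax[[3]], each = dm[1] * dm[2]), dm)
  )
}

# dense centerline (about 1 mm spacing) and unit tangents for a bundle
bundle_centerline <- function(bundle, step_mm = 1) {
  cp <- bundle$centerline_control_points_mm
  total <- arc_length(cp)
  n <- max(16L, ceiling(total / step_mm))
  pts <- resample_polyline(cp, n)
  tang <- pts[c(2:n, n), ] - pts[c(1, 1:(n - 1)), ]
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, tangents = tang)
}

# signed radial distance to an ellipsoid surface (exact for spheres):
# |p - c| * (1 - 1 / |u|) with u the radii-scaled offset
ellipsoid_radial_distance <- function(x, y, z, center, radii) {
  dx <- x - center[1]; dy <- y - center[2]; dz <- z - center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  un <- sqrt((dx / radii[1])^2 + (dy / radii[2])^2 + (dz / radii[3])^2)
  out <- r * (1 - 1 / pmax(un, 1e-12))
  out[un < 1e-12] <- -min(radii)
  out
}

hemisphere_noise <- function(spec, dm, map_index, sd) {
  # separate substreams per map and hemisphere: the contralesional stream
  # never depends on lesion parameters
  ax <- spec$midsagittal_axis
  half <- floor(dm[ax] / 2)
  noise <- array(0, dm)
  idx_lo <- slice.index(noise, ax) <= half
  set.seed(spec$rng_seed + 10L * map_index + 1L)
  noise[idx_lo] <- stats::rnorm(sum(idx_lo), sd = sd)
  set.seed(spec$rng_seed + 10L * map_index + 2L)
  noise[!idx_lo] <- stats::rnorm(sum(!idx_lo), sd = sd)
  noise
}

#' Generate a synthetic diffusion phantom
#'
#' Builds coefficient maps (FA, MD, AD, RD), a principal fiber-direction
#' field, bundle and hemisphere masks, and an ellipsoidal lesion mask with
#' the injected diffusion effect, all with known ground truth. FA equals
#' `baseline_fa` inside the bundle tubes minus the lesion effect (clipped to
#' \[0, 1\]) and is zero in the background, so the direction field is unit
#' norm wherever FA > 0. The diffusivity maps carry the baseline everywhere
#' plus the (positive) lesion effect. Deterministic for a fixed `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` object: list with `fa`, `md`, `ad`, `rd`
#'   ([scalar_volume()]), `direction_field` (4-D array, last axis length 3),
#'   `lesion_mask`, `left_hemisphere_mask`, `right_hemisphere_mask`,
#'   `bundle_masks` (list of [mask_volume()]), `truth` (list of injected
#'   parameters and derived ground truth), and `truth_streamlines`
#'   ([streamline_set()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  dm <- spec$grid_shape
  aff <- phantom_affine(spec)
  g <- voxel_center_grid(spec)

  # bundle masks and direction field from nearest centerline tangents
  dirs <- array(0, c(dm, 3))
  bundle_masks <- list()
  bundle_union <- array(FALSE, dm)
  nearest_dist <- array(Inf, dm)
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    cl <- bundle_centerline(b)
    lo <- apply(cl$points, 2, min) - b$radius_mm - max(spec$voxel_size_mm)
    hi <- apply(cl$points, 2, max) + b$radius_mm + max(spec$voxel_size_mm)
    cand <- which(g$x >= lo[1] & g$x <= hi[1] &
                    g$y >= lo[2] & g$y <= hi[2] &
                    g$z >= lo[3] & g$z <= hi[3])
    if (length(cand) == 0) next
    pts <- cbind(g$x[cand], g$y[cand], g$z[cand])
    nn <- nearest_polyline_point(pts, cl$points)
    inside <- nn$dist <= b$radius_mm
    sel <- cand[inside]
    mask <- array(FALSE, dm)
    mask[sel] <- TRUE
    bundle_masks[[paste0(b$hemisphere, "_", bi)]] <-
      mask_volume(array(as.numeric(mask), dm), aff)
    closer <- inside & (nn$dist < nearest_dist[cand])
    nearest_dist[cand[closer]] <- nn$dist[closer]
    tidx <- nn$index[closer]
    vox <- cand[closer]
    npx <- prod(dm)
    dirs[vox] <- cl$tangents[tidx, 1]
    dirs[vox + npx] <- cl$tangents[tidx, 2]
    dirs[vox + 2 * npx] <- cl$tangents[tidx, 3]
    bundle_union <- bundle_union | mask
  }

  # lesion geometry and effect, confined to the ipsilesional hemisphere so
  # contralesional data are exactly independent of the lesion parameters
  dist_mm <- ellipsoid_radial_distance(
    g$x, g$y, g$z, spec$lesion_center_mm, spec$lesion_radii_mm
  )
  lesion <- dist_mm <= 0
  coord_mid <- list(g$x, g$y, g$z)[[spec$midsagittal_axis]]
  ipsi_side <- sign(coord_mid) ==
    sign(spec$lesion_center_mm[spec$midsagittal_axis])
  fa_eff <- lesion_effect_profile(dist_mm, spec$delta_fa,
                                  spec$effect_decay_mm) * ipsi_side
  md_eff <- lesion_effect_profile(dist_mm, spec$delta_md,
                                  spec$effect_decay_mm) * ipsi_side

  # physiological right-minus-left baseline asymmetry (all maps)
  coord_ax <- list(g$x, g$y, g$z)[[spec$midsagittal_axis]]
  asym <- 1 + sign(coord_ax) * spec$hemisphere_asymmetry / 2

  fa <- array(0, dm)
  fa[bundle_union] <- (spec$baseline_fa * asym - fa_eff)[bundle_union]
  if (spec$noise_sd_fa > 0) {
    nz <- hemisphere_noise(spec, dm, 1L, spec$noise_sd_fa)
    fa[bundle_union] <- fa[bundle_union] + nz[bundle_union]
  }
  fa <- pmin(pmax(fa, 0), 1)
  fa <- array(fa, dm)

  make_diffusivity <- function(baseline, effect, map_index) {
    m <- baseline * asym + effect
    if (spec$noise_sd_md > 0) {
      m <- m + hemisphere_noise(spec, dm, map_index, spec$noise_sd_md)
    }
    array(m, dm)
  }
  md <- make_diffusivity(spec$baseline_md, md_eff, 2L)
  ad <- make_diffusivity(spec$baseline_ad, spec$ad_scale * md_eff, 3L)
  rd <- make_diffusivity(spec$baseline_rd, spec$rd_scale * md_eff, 4L)

  ax <- spec$midsagittal_axis
  half <- floor(dm[ax] / 2)
  left <- array(as.numeric(slice.index(fa, ax) <= half), dm)
  right <- array(as.numeric(slice.index(fa, ax) > half), dm)

  voxvol <- prod(spec$voxel_size_mm)
  ipsi <- if (spec$lesion_center_mm[ax] > 0) "right" else "left"

  truth_sl <- phantom_truth_streamlines(spec)

  structure(
    list(
      fa = scalar_volume(fa, aff),
      md = scalar_volume(md, aff),
      ad = scalar_volume(ad, aff),
      rd = scalar_volume(rd, aff),
      direction_field = dirs,
      lesion_mask = mask_volume(array(as.numeric(lesion), dm), aff),
      left_hemisphere_mask = mask_volume(left, aff),
      right_hemisphere_mask = mask_volume(right, aff),
      bundle_masks = bundle_masks,
      truth_streamlines = truth_sl,
      truth = list(
        spec = spec,
        ipsilesional = ipsi,
        lesion_volume_cm3 = sum(lesion) * voxvol / 1000,
        brain_volume_cm3 = prod(dm) * voxvol / 1000
      )
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s voxels, %d bundle(s), lesion %.1f cm3 (%s hemisphere)\n",
    paste(dim(x$fa$data), collapse = "x"),
    length(x$bundle_masks),
    x$truth$lesion_volume_cm3, x$truth$ipsilesional
  ))
  invisible(x)
}

# nearest point on a densified polyline for each query point (chunked)
nearest_polyline_point <- function(points, polyline) {
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_i <- rep(1L, n)
  chunk <- max(1L, floor(2e6 / nrow(polyline)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    p <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(polyline^2), "+") -
      2 * p %*% t(polyline)
    wi <- max.col(-d2, ties.method = "first")
    wd <- d2[cbind(seq_len(nrow(d2)), wi)]
    best_d2[s:e] <- wd
    best_i[s:e] <- wi
  }
  list(dist = sqrt(pmax(best_d2, 0)), index = best_i)
}

# ground-truth streamlines: centerline offset by a random in-disc vector in
# the local normal plane, transported along the bundle
phantom_truth_streamlines <- function(spec) {
  set.seed(spec$rng_seed + 5L)
  all_pts <- list()
  hemi <- character(0)
  for (b in spec$bundles) {
    cl <- bundle_centerline(b, step_mm = 2)
    tang <- cl$tangents
    # frame: e1 orthogonal to tangent (seeded from global x), e2 = t x e1
    e1 <- cbind(1, 0, 0) [rep(1, nrow(tang)), ]
    proj <- rowSums(e1 * tang)
    e1 <- e1 - tang * proj
    bad <- sqrt(rowSums(e1^2)) < 1e-6
    e1[bad, ] <- cbind(0, 0, 1)[rep(1, sum(bad)), ]
    e1 <- e1 / sqrt(rowSums(e1^2))
    e2 <- cbind(
      tang[, 2] * e1[, 3] - tang[, 3] * e1[, 2],
      tang[, 3] * e1[, 1] - tang[, 1] * e1[, 3],
      tang[, 1] * e1[, 2] - tang[, 2] * e1[, 1]
    )
    for (k in seq_len(b$n_streamlines_truth)) {
      repeat {
        off <- stats::runif(2, -b$radius_mm, b$radius_mm)
        if (sum(off^2) <= b$radius_mm^2) break
      }
      pts <- cl$points + off[1] * e1 + off[2] * e2
      all_pts[[length(all_pts) + 1]] <- pts
      hemi <- c(hemi, b$hemisphere)
    }
  }
  if (length(all_pts) == 0) {
    return(structure(list(points = list(), meta = empty_meta()),
                     class = "streamline_set"))
  }
  streamline_set(all_pts, group = hemi, bundle = hemi)
}

#' Write / read a phantom as NIfTI + JSON files
#'
#' Coefficient maps are written as float32 NIfTI, masks as uint8, the
#' direction field as a 4-D float32 NIfTI (last axis length 3), and the
#' ground-truth parameters as a JSON metadata file.
#'
#' @param phantom a [generate_phantom()] result.
#' @param directory output directory (created if needed).
#' @return `write_phantom()` returns the directory invisibly;
#'   `read_phantom()` returns a list of volumes and the truth metadata.
#' @export
write_phantom <- function(phantom, directory) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_volume(phantom$fa, p("fa.nii.gz"))
  write_volume(phantom$md, p("md.nii.gz"))
  write_volume(phantom$ad, p("ad.nii.gz"))
  write_volume(phantom$rd, p("rd.nii.gz"))
  write_volume(phantom$lesion_mask, p("lesion_mask.nii.gz"))
  write_volume(phantom$left_hemisphere_mask, p("hemisphere_left.nii.gz"))
  write_volume(phantom$right_hemisphere_mask, p("hemisphere_right.nii.gz"))
  for (nm in names(phantom$bundle_masks)) {
    write_volume(phantom$bundle_masks[[nm]],
                 p(sprintf("bundle_%s.nii.gz", nm)))
  }
  img <- RNifti::asNifti(phantom$direction_field)
  RNifti::pixdim(img) <- c(phantom$fa$voxel_size_mm, 1)
  img <- RNifti::`sform<-`(img, structure(phantom$fa$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(phantom$fa$affine, code = 2L))
  RNifti::writeNifti(img, p("directions.nii.gz"), datatype = "float")
  truth <- phantom$truth
  truth$spec <- unclass(truth$spec)
  truth$spec$bundles <- lapply(truth$spec$bundles, function(b) {
    b <- unclass(b)
    b$centerline_control_points_mm <-
      apply(b$centerline_control_points_mm, 1, identity, simplify = FALSE)
    b
  })
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(directory)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(directory) {
  p <- function(f) file.path(directory, f)
  bundles <- list.files(directory, "^bundle_.*nii\\.gz$")
  img <- RNifti::readNifti(p("directions.nii.gz"))
  list(
    fa = read_volume(p("fa.nii.gz")),
    md = read_volume(p("md.nii.gz")),
    ad = read_volume(p("ad.nii.gz")),
    rd = read_volume(p("rd.nii.gz")),
    lesion_mask = read_volume(p("lesion_mask.nii.gz"), mask = TRUE),
    left_hemisphere_mask = read_volume(p("hemisphere_left.nii.gz"),
                                       mask = TRUE),
    right_hemisphere_mask = read_volume(p("hemisphere_right.nii.gz"),
                                        mask = TRUE),
    bundle_masks = stats::setNames(
      lapply(bundles, function(f) read_volume(p(f), mask = TRUE)),
      sub("^bundle_(.*)\\.nii\\.gz$", "\\1", bundles)
    ),
    direction_field = as.array(img),
    truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  )
}

#' Generate a synthetic patient cohort
#'
#' Produces one [phantom_spec()] per subject, emulating a retrospective
#' clinical series: unilateral lesions of varying size and position (about
#' half on each side), modest inter-subject variation in healthy baseline
#' coefficients, and independent noise. Effect sizes (`delta_fa`,
#' `delta_md`, decay) are inherited from `base_spec` for every subject.
#'
#' @param n_subjects number of subjects (default 13).
#' @param base_spec template [phantom_spec()].
#' @param rng_seed cohort-level seed.
#' @param size_range multiplicative range of lesion radii across subjects.
#' @param asymmetry_sd sd of the per-subject hemispheric baseline asymmetry
#'   (relative right-minus-left difference; ~0.5% is physiological).
#' @return list of `phantom_spec`, named `S01`, `S02`, ...
#' @export
phantom_cohort <- function(n_subjects = 13, base_spec = phantom_spec(),
                           rng_seed = 1L, size_range = c(0.7, 1.25),
                           asymmetry_sd = 0.003) {
  set.seed(rng_seed)
  specs <- vector("list", n_subjects)
  ax <- base_spec$midsagittal_axis
  for (i in seq_len(n_subjects)) {
    s <- base_spec
    scale <- stats::runif(1, size_range[1], size_range[2])
    s$lesion_radii_mm <- base_spec$lesion_radii_mm * scale
    jitter <- stats::rnorm(3, sd = 3)
    jitter[ax] <- 0 # keep the lateral margin to the midline
    s$lesion_center_mm <- base_spec$lesion_center_mm + jitter
    if (i %% 2 == 0) { # mirror to the other hemisphere
      s$lesion_center_mm[ax] <- -s$lesion_center_mm[ax]
    }
    s$baseline_fa <- min(1, base_spec$baseline_fa + stats::rnorm(1, sd = 0.02))
    s$baseline_md <- base_spec$baseline_md * stats::runif(1, 0.95, 1.05)
    s$hemisphere_asymmetry <- stats::rnorm(1, sd = asymmetry_sd)
    s$rng_seed <- as.integer(rng_seed + 1000L * i)
    validate_phantom_spec(s)
    specs[[i]] <- s
  }
  stats::setNames(specs, sprintf("S%02d", seq_len(n_subjects)))
}
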