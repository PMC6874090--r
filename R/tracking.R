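#' Tracking parameters
#'
#' Parameters of the deterministic streamline tracker. Defaults follow
#' common deterministic-tractography practice for clinical DTI: FA threshold
#' 0.15, angular threshold 55 degrees, 1 mm steps, 50% smoothing of the
#' propagation direction with the previous direction, 30-300 mm length gate,
#' and 50,000 random seeds.
#'
#' @param fa_threshold terminate where FA drops below this (0-1).
#' @param angular_threshold_deg terminate when the field orientation turns
#'   by more than this relative to the incoming direction (degrees, 0-90).
#' @param step_size_mm propagation step in mm.
#' @param smoothing_fraction weight of the previous direction in the convex
#'   combination `new = normalize((1 - f) * raw + f * previous)`.
#' @param min_length_mm,max_length_mm retained arc-length range.
#' @param n_seeds number of random seeds.
#' @param rng_seed integer seed for seed placement.
#' @param direction_mode `"nearest"` voxel lookup of the direction field
#'   (default) or `"trilinear"` interpolation.
#' @return a `tracking_params` list.
#' @export
tracking_params <- function(fa_threshold = 0.15,
                            angular_threshold_deg = 55,
                            step_size_mm = 1,
                            smoothing_fraction = 0.5,
                            min_length_mm = 30,
                            max_length_mm = 300,
                            n_seeds = 50000L,
                            rng_seed = 0L,
                            direction_mode = c("nearest", "trilinear")) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(
    fa_threshold >= 0, fa_threshold <= 1,
    angular_threshold_deg > 0, angular_threshold_deg < 90,
    smoothing_fraction >= 0, smoothing_fraction < 1,
    step_size_mm > 0,
    min_length_mm > 0, min_length_mm < max_length_mm,
    n_seeds >= 1
  )
  structure(
    list(
      fa_threshold = fa_threshold,
      angular_threshold_deg = angular_threshold_deg,
      step_size_mm = step_size_mm,
      smoothing_fraction = smoothing_fraction,
      min_length_mm = min_length_mm,
      max_length_mm = max_length_mm,
      n_seeds = as.integer(n_seeds),
      rng_seed = as.integer(rng_seed),
      direction_mode = direction_mode
    ),
    class = "tracking_params"
  )
}

# nearest-voxel lookups against a 3-D array + affine, returning NA outside
lookup_fa <- function(points, fa_map) {
  sample_map(points, fa_map, mode = "nearest")
}

lookup_directions <- function(points, dirs, fa_map, mode = "nearest") {
  dm <- dim(fa_map$data)
  npx <- prod(dm)
  if (mode == "trilinear") {
    comps <- vapply(1:3, function(k) {
      sample_map(points, scalar_volume(array(dirs[(1 + (k - 1) * npx):
                                                    (k * npx)], dm),
                                       fa_map$affine),
                 mode = "trilinear")
    }, numeric(nrow(points)))
    comps <- matrix(comps, ncol = 3)
    comps[is.na(comps)] <- 0
    return(comps)
  }
  idx <- world_to_voxel(points, fa_map)
  inside <- attr(idx, "inside")
  out <- matrix(0, nrow(points), 3)
  if (any(inside)) {
    ii <- idx[inside, , drop = FALSE]
    lin <- ii[, 1] + (ii[, 2] - 1) * dm[1] + (ii[, 3] - 1) * dm[1] * dm[2]
    out[inside, 1] <- dirs[lin]
    out[inside, 2] <- dirs[lin + npx]
    out[inside, 3] <- dirs[lin + 2 * npx]
  }
  out
}

# one propagation half: from seed positions P0 along initial directions D0
propagate_half <- function(P0, D0, dirs, fa_map, params) {
  cos_thr <- cos(params$angular_threshold_deg * pi / 180)
  f <- params$smoothing_fraction
  max_steps <- ceiling(params$max_length_mm / params$step_size_mm) + 1L
  n <- nrow(P0)
  alive <- seq_len(n)
  P <- P0
  D <- D0
  rec_id <- vector("list", max_steps)
  rec_pos <- vector("list", max_steps)
  for (step in seq_len(max_steps)) {
    if (length(alive) == 0) break
    raw <- lookup_directions(P, dirs, fa_map, params$direction_mode)
    nrm <- sqrt(rowSums(raw^2))
    ok <- nrm > 1e-8
    if (any(ok)) {
      raw[ok, ] <- raw[ok, , drop = FALSE] / nrm[ok]
      flip <- rowSums(raw * D) < 0
      raw[flip, ] <- -raw[flip, , drop = FALSE]
      # angular gate on the raw field orientation vs the incoming direction;
      # smoothing (below) can only reduce the turning angle further
      ok <- ok & rowSums(raw * D) >= cos_thr
      sm <- (1 - f) * raw + f * D
      smn <- sqrt(rowSums(sm^2))
      ok <- ok & smn > 1e-8
      sm[ok, ] <- sm[ok, , drop = FALSE] / smn[ok]
      cand <- P + params$step_size_mm * sm
      fa <- lookup_fa(cand, fa_map)
      ok <- ok & !is.na(fa) & fa >= params$fa_threshold
    }
    if (!any(ok)) break
    alive <- alive[ok]
    P <- cand[ok, , drop = FALSE]
    D <- sm[ok, , drop = FALSE]
    rec_id[[step]] <- alive
    rec_pos[[step]] <- P
  }
  list(id = unlist(rec_id), pos = do.call(rbind, rec_pos))
}

#' Deterministic streamline tracking on a principal-direction field
#'
#' Seeds are placed uniformly at random inside seed-mask voxels (random
#' sub-voxel position). From each seed the track is propagated
#' bidirectionally: at each step the field direction at the current position
#' is sign-aligned with the incoming direction, combined with the previous
#' direction (`smoothing_fraction`), and renormalized; propagation stops
#' when FA falls below the threshold, the turning angle exceeds the angular
#' threshold, the field vanishes, or the track leaves the grid. The two
#' half-tracks are concatenated and tracks with arc length outside
#' `[min_length_mm, max_length_mm]` are discarded. Deterministic for a fixed
#' `rng_seed`.
#'
#' @param direction_field 4-D array (grid dims x 3) of unit principal
#'   directions (zero where undefined), sharing geometry with `fa_map`.
#' @param fa_map [scalar_volume()] of fractional anisotropy.
#' @param seed_mask [mask_volume()] of allowed seed voxels.
#' @param params a [tracking_params()].
#' @return a [streamline_set()]; attribute `n_seeds` records the seed count.
#' @export
track <- function(direction_field, fa_map, seed_mask,
                  params = tracking_params()) {
  stopifnot(inherits(fa_map, "scalar_volume"),
            inherits(seed_mask, "mask_volume"),
            inherits(params, "tracking_params"))
  dm <- dim(fa_map$data)
  stopifnot(identical(dim(direction_field), c(dm, 3L)) ||
              identical(dim(direction_field), c(dm, 3)))
  empty <- function() {
    out <- structure(list(points = list(), meta = empty_meta()),
                     class = "streamline_set")
    attr(out, "n_seeds") <- params$n_seeds
    out
  }
  if (all(direction_field == 0)) {
    warning("direction field is identically zero; no streamlines")
    return(empty())
  }
  seed_vox <- which(seed_mask$data != 0, arr.ind = TRUE)
  if (nrow(seed_vox) == 0) stop("seed mask is empty", call. = FALSE)

  set.seed(params$rng_seed)
  pick <- sample.int(nrow(seed_vox), params$n_seeds, replace = TRUE)
  offs <- matrix(stats::runif(3 * params$n_seeds, -0.5, 0.5), ncol = 3)
  cont <- seed_vox[pick, , drop = FALSE] - 1 + offs
  seeds <- t(fa_map$affine[1:3, 1:3] %*% t(cont) + fa_map$affine[1:3, 4])

  fa0 <- lookup_fa(seeds, fa_map)
  d0 <- lookup_directions(seeds, direction_field, fa_map,
                          params$direction_mode)
  nrm <- sqrt(rowSums(d0^2))
  live <- !is.na(fa0) & fa0 >= params$fa_threshold & nrm > 1e-8
  if (!any(live)) {
    warning("no viable seeds (FA below threshold or undefined direction)")
    return(empty())
  }
  seeds <- seeds[live, , drop = FALSE]
  d0 <- d0[live, , drop = FALSE] / nrm[live]
  m <- nrow(seeds)

  fwd <- propagate_half(seeds, d0, direction_field, fa_map, params)
  bwd <- propagate_half(seeds, -d0, direction_field, fa_map, params)

  fwd_pts <- split_positions(fwd, m)
  bwd_pts <- split_positions(bwd, m)

  pts <- vector("list", m)
  keep <- logical(m)
  for (i in seq_len(m)) {
    b <- bwd_pts[[i]]
    p <- rbind(
      if (!is.null(b)) b[rev(seq_len(nrow(b))), , drop = FALSE],
      seeds[i, , drop = FALSE],
      fwd_pts[[i]]
    )
    if (nrow(p) < 2) next
    len <- arc_length(p)
    if (len >= params$min_length_mm && len <= params$max_length_mm) {
      keep[i] <- TRUE
      pts[[i]] <- p
    }
  }
  if (!any(keep)) {
    warning("no streamlines satisfied the length gate")
    return(empty())
  }
  out <- streamline_set(pts[keep])
  attr(out, "n_seeds") <- params$n_seeds
  out
}

split_positions <- function(half, m) {
  out <- vector("list", m)
  if (is.null(half$pos) || length(half$id) == 0) return(out)
  ord <- order(half$id) # stable: preserves step order within id
  sp <- split(seq_along(half$id)[ord], half$id[ord])
  for (nm in names(sp)) {
    out[[as.integer(nm)]] <- half$pos[sp[[nm]], , drop = FALSE]
  }
  out
}
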