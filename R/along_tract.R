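#' Common node count for along-tract resampling
#'
#' All tracts in one along-tract analysis are resampled to a shared node
#' count so scalar values can be compared position by position. The count is
#' the mean number of points per streamline, pooled over all supplied sets
#' (across subjects and groups), rounded to the nearest integer (minimum 2).
#'
#' @param ... [streamline_set()] objects (or lists of them).
#' @return integer node count.
#' @export
common_node_count <- function(...) {
  sets <- list(...)
  sets <- unlist(lapply(sets, function(s) {
    if (inherits(s, "streamline_set")) list(s) else s
  }), recursive = FALSE)
  counts <- unlist(lapply(sets, function(s) {
    vapply(s$points, nrow, integer(1))
  }))
  if (length(counts) == 0) stop("no streamlines supplied", call. = FALSE)
  max(2L, as.integer(round(mean(counts))))
}

#' Resample a polyline to equally spaced arc-length nodes
#'
#' Fits a natural cubic spline through the points, parameterized by
#' cumulative chord length, then places `n_nodes` nodes at equal arc-length
#' spacing along the densely evaluated curve. Endpoints are preserved
#' exactly; for smooth curves total arc length is preserved well below 1%.
#'
#' @param streamline n x 3 matrix of points (n >= 2).
#' @param n_nodes number of output nodes (>= 2).
#' @return `n_nodes` x 3 matrix.
#' @examples
#' theta <- seq(0, pi / 2, length.out = 25)
#' arc <- cbind(10 * cos(theta), 10 * sin(theta), 0)
#' nrow(resample_streamline(arc, 100))
#' @export
resample_streamline <- function(streamline, n_nodes) {
  resample_polyline(streamline, n_nodes)
}

resample_polyline <- function(p, n_nodes) {
  p <- as_points_matrix(p)
  n <- nrow(p)
  if (n < 2) stop("streamline needs >= 2 points", call. = FALSE)
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  if (any(seg == 0)) stop("degenerate streamline (repeated points)",
                          call. = FALSE)
  s <- c(0, cumsum(seg))
  n_dense <- max(10L * n_nodes, 20L * n, 200L)
  sd_grid <- seq(0, s[n], length.out = n_dense)
  dense <- if (n == 2) {
    cbind(
      stats::approx(s, p[, 1], xout = sd_grid)$y,
      stats::approx(s, p[, 2], xout = sd_grid)$y,
      stats::approx(s, p[, 3], xout = sd_grid)$y
    )
  } else {
    cbind(
      stats::spline(s, p[, 1], xout = sd_grid, method = "natural")$y,
      stats::spline(s, p[, 2], xout = sd_grid, method = "natural")$y,
      stats::spline(s, p[, 3], xout = sd_grid, method = "natural")$y
    )
  }
  dseg <- sqrt(rowSums((dense[-1, , drop = FALSE] -
                          dense[-n_dense, , drop = FALSE])^2))
  darc <- c(0, cumsum(dseg))
  targets <- seq(0, darc[n_dense], length.out = n_nodes)
  out <- cbind(
    stats::approx(darc, dense[, 1], xout = targets, ties = "ordered")$y,
    stats::approx(darc, dense[, 2], xout = targets, ties = "ordered")$y,
    stats::approx(darc, dense[, 3], xout = targets, ties = "ordered")$y
  )
  out[1, ] <- p[1, ]
  out[n_nodes, ] <- p[n, ]
  out
}

#' Normalize coefficient values to the contralesional mean
#'
#' Along-tract values are expressed relative to the patient's own healthy
#' hemisphere: `value / contralesional_mean`, so the contralesional group
#' mean is ~1.
#'
#' @param values numeric vector.
#' @param contralesional_mean positive scalar.
#' @return normalized values.
#' @export
normalize_to_contralesional <- function(values, contralesional_mean) {
  if (!is.finite(contralesional_mean) || contralesional_mean <= 0) {
    stop("contralesional_mean must be > 0", call. = FALSE)
  }
  values / contralesional_mean
}

mask_boundary_voxels <- function(mask) {
  m <- mask$data != 0
  dm <- dim(m)
  shift_out <- function(ax, dir) {
    # TRUE where the face neighbor along ax/dir is outside the mask
    idx_src <- lapply(dm, seq_len)
    idx_src[[ax]] <- idx_src[[ax]] + dir
    out <- array(TRUE, dm) # grid edge counts as outside
    valid <- idx_src[[ax]] >= 1 & idx_src[[ax]] <= dm[ax]
    sub <- lapply(dm, seq_len)
    sub[[ax]] <- which(valid)
    src <- idx_src
    src[[ax]] <- idx_src[[ax]][valid]
    out[sub[[1]], sub[[2]], sub[[3]]] <- !m[src[[1]], src[[2]], src[[3]]]
    out
  }
  any_out <- array(FALSE, dm)
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    any_out <- any_out | shift_out(ax, dir)
  }
  boundary <- m & any_out
  which(boundary, arr.ind = TRUE)
}

#' Signed Euclidean distance to a lesion boundary
#'
#' For each world-coordinate point, the minimum Euclidean distance (mm,
#' anisotropy-aware since voxel centers carry true world coordinates) to the
#' nearest lesion boundary-voxel center: positive outside the lesion,
#' negative inside. Boundary voxels are mask voxels with at least one
#' non-mask face neighbor (grid edges count as outside).
#'
#' @param points n x 3 matrix of world points (mm).
#' @param lesion_mask a non-empty [mask_volume()].
#' @return numeric vector of signed distances in mm.
#' @export
signed_distance <- function(points, lesion_mask) {
  stopifnot(inherits(lesion_mask, "mask_volume"))
  points <- as_points_matrix(points)
  if (sum(lesion_mask$data) == 0) stop("lesion mask is empty", call. = FALSE)
  bidx <- mask_boundary_voxels(lesion_mask)
  bw <- voxel_to_world(bidx, lesion_mask)
  n <- nrow(points)
  d <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(bw)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    p <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(bw^2), "+") - 2 * p %*% t(bw)
    d[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  inside <- sample_map(points, lesion_mask, mode = "nearest")
  inside <- !is.na(inside) & inside > 0
  d[inside] <- -d[inside]
  d
}

#' Mirror a lesion mask across the midsagittal plane
#'
#' Flips the mask voxelwise along the given axis (about the grid's center
#' plane, taken as the midsagittal plane), placing the lesion at the
#' homologous contralesional position for use as a within-subject control.
#' Voxel count is preserved exactly and the operation is an involution.
#'
#' @param lesion_mask a [mask_volume()] entirely on one side of the plane.
#' @param midsagittal_axis axis index (1-3).
#' @return flipped [mask_volume()].
#' @export
flip_lesion <- function(lesion_mask, midsagittal_axis = 1) {
  stopifnot(inherits(lesion_mask, "mask_volume"),
            midsagittal_axis %in% 1:3)
  dm <- dim(lesion_mask$data)
  ax <- midsagittal_axis
  half <- floor(dm[ax] / 2)
  side <- slice.index(lesion_mask$data, ax) <= half
  m <- lesion_mask$data != 0
  if (any(m & side) && any(m & !side)) {
    warning("lesion mask straddles the midsagittal plane")
  }
  idx <- lapply(dm, seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  flipped <- lesion_mask$data[idx[[1]], idx[[2]], idx[[3]]]
  mask_volume(array(flipped, dm), lesion_mask$affine)
}

#' Along-tract distance-value profile
#'
#' Resamples every streamline in the set to `n_nodes` equal arc-length
#' nodes, samples the coefficient map at the nodes (nearest-voxel by
#' default, matching the voxel-set extraction used elsewhere; trilinear is
#' available but blends with the background at sharp tissue boundaries),
#' normalizes by the contralesional mean, and attaches the signed distance
#' of each node to the lesion boundary. For the contralesional control
#' group, pass the flipped lesion ([flip_lesion()]) as `lesion_mask`.
#'
#' @param set a [streamline_set()].
#' @param volume coefficient map ([scalar_volume()]).
#' @param lesion_mask lesion (or flipped lesion) [mask_volume()].
#' @param n_nodes common node count (see [common_node_count()]).
#' @param contralesional_mean normalization constant (default 1 = none).
#' @param sample_mode `"nearest"` (default) or `"trilinear"`.
#' @return tibble with columns `streamline`, `subject`, `group`, `node`,
#'   `distance_mm`, `value`.
#' @export
tract_distance_profile <- function(set, volume, lesion_mask, n_nodes,
                                   contralesional_mean = 1,
                                   sample_mode = "nearest") {
  stopifnot(inherits(set, "streamline_set"))
  if (n_streamlines(set) == 0) {
    return(tibble::tibble(
      streamline = integer(), subject = character(), group = character(),
      node = integer(), distance_mm = numeric(), value = numeric()
    ))
  }
  nodes <- lapply(set$points, resample_polyline, n_nodes = n_nodes)
  all_pts <- do.call(rbind, nodes)
  vals <- sample_map(all_pts, volume, mode = sample_mode)
  vals <- normalize_to_contralesional(vals, contralesional_mean)
  dist <- signed_distance(all_pts, lesion_mask)
  tibble::tibble(
    streamline = rep(set$meta$streamline, each = n_nodes),
    subject = rep(set$meta$subject, each = n_nodes),
    group = rep(set$meta$group, each = n_nodes),
    node = rep(seq_len(n_nodes), times = n_streamlines(set)),
    distance_mm = dist,
    value = vals
  )
}

#' Binned along-tract profile with confidence intervals
#'
#' Bins node values by signed distance to the lesion boundary and summarizes
#' each (bin, group) cell with its mean and 95% confidence interval
#' `mean +/- t[0.975, n-1] * SEM` (z critical value available via
#' `ci = "z"`). Bins with fewer than `min_count` values are flagged `low_n`
#' (distant bins hold few nodes and are predictably noisy).
#'
#' @param profile tibble from [tract_distance_profile()] (rows from several
#'   groups/subjects may be bound together).
#' @param bin_width_mm bin width in mm (default 2).
#' @param ci_level confidence level (default 0.95).
#' @param ci `"t"` or `"z"`.
#' @param min_count flag threshold for low-occupancy bins.
#' @return a `binned_profile` tibble: `bin_center_mm`, `group`, `mean`,
#'   `ci_low`, `ci_high`, `n`, `low_n`.
#' @export
binned_profile <- function(profile, bin_width_mm = 2, ci_level = 0.95,
                           ci = c("t", "z"), min_count = 3) {
  ci <- match.arg(ci)
  stopifnot(bin_width_mm > 0, nrow(profile) > 0)
  keep <- is.finite(profile$distance_mm) & is.finite(profile$value)
  profile <- profile[keep, , drop = FALSE]
  lo <- floor(min(profile$distance_mm) / bin_width_mm) * bin_width_mm
  bin <- lo + bin_width_mm *
    floor((profile$distance_mm - lo) / bin_width_mm)
  profile$bin_center_mm <- bin + bin_width_mm / 2
  alpha <- 1 - ci_level
  out <- profile |>
    dplyr::group_by(.data$bin_center_mm, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sem = ifelse(.data$n > 1, .data$sd / sqrt(.data$n), 0),
      crit = if (ci == "t") {
        ifelse(.data$n > 1,
               stats::qt(1 - alpha / 2, pmax(.data$n - 1, 1)), 0)
      } else {
        stats::qnorm(1 - alpha / 2)
      },
      ci_low = .data$mean - .data$crit * .data$sem,
      ci_high = .data$mean + .data$crit * .data$sem,
      low_n = .data$n < min_count
    ) |>
    dplyr::select("bin_center_mm", "group", "mean", "ci_low", "ci_high",
                  "n", "low_n") |>
    dplyr::arrange(.data$group, .data$bin_center_mm)
  attr(out, "bin_width_mm") <- bin_width_mm
  class(out) <- c("binned_profile", class(out))
  out
}

#' Confidence-interval overlap flags between two groups
#'
#' For every distance bin where both groups are present, flags whether the
#' two 95% confidence intervals are disjoint (`TRUE` = non-overlapping =
#' evidence of a group difference at that distance). Touching intervals
#' count as overlapping (closed-interval convention). Bins missing either
#' group are dropped, as are bins where either group is `low_n`: a CI over
#' fewer than `min_count` values is degenerate and supports no overlap
#' statement.
#'
#' @param binned a [binned_profile()].
#' @param group_pair character vector of two group labels.
#' @return tibble `bin_center_mm`, `group1`, `group2`, `nonoverlap`.
#' @export
ci_overlap_flags <- function(binned, group_pair) {
  stopifnot(length(group_pair) == 2)
  a <- binned[binned$group == group_pair[1] & !binned$low_n, ]
  b <- binned[binned$group == group_pair[2] & !binned$low_n, ]
  m <- dplyr::inner_join(
    a, b,
    by = "bin_center_mm", suffix = c("_1", "_2")
  )
  tibble::tibble(
    bin_center_mm = m$bin_center_mm,
    group1 = group_pair[1],
    group2 = group_pair[2],
    nonoverlap = m$ci_low_1 > m$ci_high_2 | m$ci_low_2 > m$ci_high_1
  )
}
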