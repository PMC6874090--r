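#' ROI/ROA selection recipe
#'
#' Defines one analysis group by inclusion/exclusion masks: a streamline is
#' selected iff it intersects every ROI mask and no ROA mask (AND across
#' ROIs, NOT-ANY across ROAs). The canonical recipes are:
#' \describe{
#'   \item{C}{ROI contralesional bundle; ROA ipsilesional hemisphere.}
#'   \item{I}{ROI ipsilesional bundle; ROA contralesional hemisphere.}
#'   \item{IE}{ROI ipsilesional bundle; ROA contralesional hemisphere and
#'     lesion (lesion-avoiding tracks).}
#'   \item{II}{ROI ipsilesional bundle and lesion; ROA contralesional
#'     hemisphere (lesion-crossing tracks).}
#' }
#' A recipe whose ROI voxels are entirely contained in the ROA union would
#' select nothing by construction and is rejected.
#'
#' @param label group label (e.g. `"C"`, `"I"`, `"IE"`, `"II"`, or a
#'   hemisphere name).
#' @param roi_masks list of [mask_volume()] a streamline must intersect.
#' @param roa_masks list of [mask_volume()] a streamline must avoid.
#' @return a `selection_recipe` list.
#' @export
selection_recipe <- function(label, roi_masks, roa_masks = list()) {
  if (inherits(roi_masks, "mask_volume")) roi_masks <- list(roi_masks)
  if (inherits(roa_masks, "mask_volume")) roa_masks <- list(roa_masks)
  stopifnot(length(roi_masks) >= 1)
  lapply(c(roi_masks, roa_masks), function(m) {
    stopifnot(inherits(m, "mask_volume"))
  })
  if (length(roa_masks) > 0) {
    roa_union <- Reduce(`|`, lapply(roa_masks, function(m) m$data != 0))
    for (m in roi_masks) {
      roi <- m$data != 0
      if (any(roi) && all(roa_union[roi])) {
        stop("recipe '", label, "' has an ROI fully inside the ROA union; ",
             "it would select nothing", call. = FALSE)
      }
    }
  }
  structure(
    list(label = label, roi_masks = roi_masks, roa_masks = roa_masks),
    class = "selection_recipe"
  )
}

#' Does a streamline intersect a mask?
#'
#' The streamline is densified to a step of at most half the minimum voxel
#' size before membership testing, so a segment crossing a thin mask between
#' two stored points is still detected.
#'
#' @param streamline n x 3 matrix (world mm).
#' @param mask a [mask_volume()].
#' @return logical scalar.
#' @export
streamline_intersects <- function(streamline, mask) {
  stopifnot(inherits(mask, "mask_volume"))
  step <- min(mask$voxel_size_mm) / 2
  pts <- densify_polyline(streamline, step)
  vals <- sample_map(pts, mask, mode = "nearest")
  any(!is.na(vals) & vals > 0)
}

# densify every streamline once; reusable across mask tests
densified_set <- function(set, step) {
  dens <- lapply(set$points, densify_polyline, max_step_mm = step)
  counts <- vapply(dens, nrow, integer(1))
  list(
    points = do.call(rbind, dens),
    idx = factor(rep.int(seq_along(dens), counts),
                 levels = seq_along(dens)),
    step = step
  )
}

dens_mask_hits <- function(dens, mask) {
  vals <- sample_map(dens$points, mask, mode = "nearest")
  hit <- !is.na(vals) & vals > 0
  as.vector(tapply(hit, dens$idx, any))
}

# densified mask membership for every streamline at once
set_intersections <- function(set, mask, dens = NULL) {
  if (is.null(dens)) {
    dens <- densified_set(set, min(mask$voxel_size_mm) / 2)
  }
  dens_mask_hits(dens, mask)
}

#' Select streamlines with a recipe
#'
#' Retains exactly the streamlines that intersect all ROI masks and none of
#' the ROA masks, and attaches the recipe label as the group. An empty
#' result is returned with a warning (a lesion filling, e.g., a ventricle
#' can legitimately prevent any track from crossing it).
#'
#' @param set a [streamline_set()].
#' @param recipe a [selection_recipe()].
#' @return a [streamline_set()] with `group` set to the recipe label.
#' @export
select_streamlines <- function(set, recipe) {
  stopifnot(inherits(set, "streamline_set"),
            inherits(recipe, "selection_recipe"))
  if (n_streamlines(set) == 0) {
    warning("selection '", recipe$label, "' on an empty streamline set")
    out <- set
    out$meta$group <- character(0)
    return(out)
  }
  step <- min(vapply(c(recipe$roi_masks, recipe$roa_masks),
                     function(m) min(m$voxel_size_mm), numeric(1))) / 2
  dens <- densified_set(set, step)
  keep <- rep(TRUE, n_streamlines(set))
  for (m in recipe$roi_masks) keep <- keep & dens_mask_hits(dens, m)
  for (m in recipe$roa_masks) keep <- keep & !dens_mask_hits(dens, m)
  out <- filter_streamlines(set, keep)
  out$meta$group <- rep(recipe$label, n_streamlines(out))
  if (n_streamlines(out) == 0) {
    warning("selection '", recipe$label, "' returned no streamlines")
  }
  out
}

#' Extract diffusion values at tract voxels
#'
#' Collects map values over the voxels visited by the streamline set
#' (densified traversal, floor-convention voxel membership). With
#' `dedupe = TRUE` (default) each voxel contributes once — "tract voxels"
#' read as a voxel set; with `dedupe = FALSE` every visit contributes.
#'
#' @param set a [streamline_set()].
#' @param volume coefficient map ([scalar_volume()]).
#' @param dedupe logical; count each voxel once (default) or per visit.
#' @param coefficient optional coefficient name stored alongside values.
#' @return tibble with columns `coefficient`, `value` and attribute
#'   `n_voxels`.
#' @export
extract_tract_values <- function(set, volume, dedupe = TRUE,
                                 coefficient = NA_character_) {
  stopifnot(inherits(set, "streamline_set"),
            inherits(volume, "scalar_volume"))
  step <- min(volume$voxel_size_mm) / 2
  lin <- integer(0)
  if (n_streamlines(set) > 0) {
    dens <- lapply(set$points, densify_polyline, max_step_mm = step)
    lin <- points_to_linear_voxels(do.call(rbind, dens), volume)
    if (dedupe) {
      lin <- unique(lin)
    } else {
      # per-visit: collapse consecutive duplicates within the densified
      # traversal so densification resolution does not inflate counts
      counts <- vapply(dens, nrow, integer(1))
      idx <- rep.int(seq_along(dens), counts)
      keep <- c(TRUE, diff(lin) != 0 | diff(idx) != 0)
      lin <- lin[keep]
    }
  }
  vals <- volume$data[lin]
  out <- tibble::tibble(
    coefficient = rep(coefficient, length(vals)),
    value = as.numeric(vals)
  )
  attr(out, "n_voxels") <- length(unique(lin))
  out
}

#' Min-max normalization to the unit interval
#'
#' `(v - min) / (max - min)`, spanning exactly \[0, 1\]. Applied per subject
#' and per coefficient across all selection groups jointly, so groups stay
#' comparable within a subject.
#'
#' @param values numeric vector with at least two distinct values.
#' @return normalized values in \[0, 1\].
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(values) {
  r <- range(values, na.rm = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("min-max normalization undefined for constant input", call. = FALSE)
  }
  (values - r[1]) / (r[2] - r[1])
}
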