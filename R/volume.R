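#' Scalar and mask volumes
#'
#' A `scalar_volume` is a 3-D scalar field (one diffusion coefficient such as
#' FA or MD) together with its voxel-to-world geometry: a 4x4 affine mapping
#' zero-based voxel indices to world coordinates in mm (RAS), as stored in
#' NIfTI-1 headers. A `mask_volume` is the binary special case used for
#' lesion segmentations, hemisphere labels and bundle ROIs.
#'
#' Within R, voxel indices are 1-based (`data[i, j, k]`); the affine applies
#' to the zero-based index, and the conversion helpers
#' [world_to_voxel()]/[voxel_to_world()] handle the offset. World coordinates
#' at a voxel's center correspond to an integral continuous voxel coordinate
#' (voxel-center convention).
#'
#' @param data numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix; last row `c(0, 0, 0, 1)`.
#' @return A `scalar_volume` (or `mask_volume`) object: a list with elements
#'   `data`, `affine` and `voxel_size_mm`.
#' @examples
#' vol <- scalar_volume(array(0, c(16, 16, 16)), diag(4))
#' vol$voxel_size_mm
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  affine <- validate_affine(affine)
  structure(
    list(
      data = data,
      affine = affine,
      voxel_size_mm = affine_voxel_size(affine)
    ),
    class = "scalar_volume"
  )
}

#' @rdname scalar_volume
#' @export
mask_volume <- function(data, affine = diag(4)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  data <- array(as.numeric(data != 0), dim(data))
  vol <- scalar_volume(data, affine)
  class(vol) <- c("mask_volume", class(vol))
  vol
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    stop("affine must be a 4x4 matrix", call. = FALSE)
  }
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-6) {
    stop("last affine row must be (0, 0, 0, 1)", call. = FALSE)
  }
  d <- abs(det(affine[1:3, 1:3]))
  if (!is.finite(d) || d < 1e-12) {
    stop("affine is not invertible", call. = FALSE)
  }
  storage.mode(affine) <- "double"
  affine
}

affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' @export
print.scalar_volume <- function(x, ...) {
  kind <- if (inherits(x, "mask_volume")) "mask_volume" else "scalar_volume"
  cat(sprintf(
    "<%s> %s voxels @ %s mm\n", kind,
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$voxel_size_mm, 4), collapse = "x")
  ))
  if (kind == "mask_volume") {
    cat(sprintf("  %d voxels set\n", sum(x$data != 0)))
  } else {
    cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} that preserve the full affine (sform)
#' and return package-native volume objects. On read, a mask is binarized at
#' a threshold of 0.5 if the stored values are not already 0/1.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param mask logical; read as a binary [mask_volume()]?
#' @return `read_volume()` returns a [scalar_volume()] or [mask_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  dat <- as.array(img)
  if (length(dim(dat)) == 4 && dim(dat)[4] == 1) dat <- dat[, , , 1]
  if (length(dim(dat)) != 3) {
    stop("expected a 3-D volume in ", path, " (got ",
         length(dim(dat)), " dims)", call. = FALSE)
  }
  if (mask) {
    vals <- unique(as.vector(dat))
    if (!all(vals %in% c(0, 1))) dat <- array(dat >= 0.5, dim(dat))
    mask_volume(dat, affine)
  } else {
    scalar_volume(dat, affine)
  }
}

#' @rdname read_volume
#' @param volume a [scalar_volume()] or [mask_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "scalar_volume"))
  datatype <- if (inherits(volume, "mask_volume")) "uint8" else "float"
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  storage.mode(points) <- "double"
  points
}

#' Convert between world (mm) and voxel coordinates
#'
#' `world_to_voxel()` maps world points to voxel indices using the volume's
#' affine: the continuous (zero-based) voxel coordinate is computed from the
#' inverse affine, and the containing voxel is its floor, so a voxel owns the
#' half-open cube starting at its own center. Returned indices are 1-based
#' for direct use with R arrays; indices outside the grid are returned as-is
#' and flagged in the `inside` attribute. `voxel_to_world()` maps 1-based
#' voxel indices to the world coordinates of the voxel centers.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param volume a [scalar_volume()].
#' @param continuous logical; return the continuous zero-based coordinate
#'   instead of the integral 1-based index.
#' @return n x 3 matrix; for `world_to_voxel()` with `continuous = FALSE` an
#'   integer matrix with attribute `inside` (logical vector).
#' @export
world_to_voxel <- function(points, volume, continuous = FALSE) {
  points <- as_points_matrix(points)
  inv <- solve(volume$affine)
  cont <- t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
  if (continuous) return(cont)
  idx <- floor(cont) + 1
  dm <- dim(volume$data)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
    idx[, 2] >= 1 & idx[, 2] <= dm[2] &
    idx[, 3] >= 1 & idx[, 3] <= dm[3]
  storage.mode(idx) <- "integer"
  attr(idx, "inside") <- inside
  idx
}

#' @rdname world_to_voxel
#' @param indices n x 3 matrix of 1-based voxel indices.
#' @export
voxel_to_world <- function(indices, volume) {
  indices <- as_points_matrix(indices)
  t(volume$affine[1:3, 1:3] %*% t(indices - 1) + volume$affine[1:3, 4])
}

#' Sample a volume at world-coordinate points
#'
#' `nearest` returns the value of the containing voxel (floor convention, see
#' [world_to_voxel()]); `trilinear` interpolates the 8 surrounding voxel
#' centers. Points outside the grid yield `NA`.
#'
#' @inheritParams world_to_voxel
#' @param mode `"nearest"` or `"trilinear"`.
#' @return numeric vector of sampled values, `NA` where outside.
#' @export
sample_map <- function(points, volume, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  points <- as_points_matrix(points)
  dm <- dim(volume$data)
  out <- rep(NA_real_, nrow(points))
  if (nrow(points) == 0) return(out)
  if (mode == "nearest") {
    idx <- world_to_voxel(points, volume)
    inside <- attr(idx, "inside")
    if (any(inside)) {
      out[inside] <- volume$data[idx[inside, , drop = FALSE]]
    }
    return(out)
  }
  cont <- world_to_voxel(points, volume, continuous = TRUE)
  # interpolation defined on the lattice of voxel centers [0, dim-1]
  inside <- cont[, 1] >= 0 & cont[, 1] <= dm[1] - 1 &
    cont[, 2] >= 0 & cont[, 2] <= dm[2] - 1 &
    cont[, 3] >= 0 & cont[, 3] <= dm[3] - 1
  if (!any(inside)) return(out)
  cc <- cont[inside, , drop = FALSE]
  lo <- pmin(floor(cc), rep(dm, each = nrow(cc)) - 2)
  lo <- pmax(lo, 0)
  fr <- cc - lo
  acc <- numeric(nrow(cc))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    ind <- cbind(lo[, 1] + dx, lo[, 2] + dy, lo[, 3] + dz) + 1
    acc <- acc + w * volume$data[ind]
  }
  out[inside] <- acc
  out
}

#' Linear voxel indices visited by a set of world points
#'
#' Internal helper: floor-convention voxel membership, dropping points that
#' fall outside the grid.
#' @noRd
points_to_linear_voxels <- function(points, volume) {
  idx <- world_to_voxel(points, volume)
  inside <- attr(idx, "inside")
  idx <- idx[inside, , drop = FALSE]
  dm <- dim(volume$data)
  as.vector(idx[, 1] + (idx[, 2] - 1) * dm[1] +
    (idx[, 3] - 1) * dm[1] * dm[2])
}
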