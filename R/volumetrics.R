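#' Lesion volume from a binary mask
#'
#' Voxel count times voxel volume, reported in cm^3.
#'
#' @param mask a [mask_volume()].
#' @return volume in cm^3.
#' @examples
#' m <- mask_volume(array(1, c(16, 16, 16)), diag(4))
#' lesion_volume(m)
#' @export
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data != 0) * prod(mask$voxel_size_mm) / 1000
}

#' Percent tumor volume
#'
#' `100 * lesion / brain`, the lesion volume as a percentage of whole-brain
#' volume.
#'
#' @param lesion_cm3 lesion volume (cm^3).
#' @param brain_cm3 brain volume (cm^3, > 0).
#' @return percentage in \[0, 100\].
#' @export
percent_tumor_volume <- function(lesion_cm3, brain_cm3) {
  if (any(brain_cm3 <= 0)) stop("brain volume must be > 0", call. = FALSE)
  if (any(lesion_cm3 < 0) || any(lesion_cm3 > brain_cm3)) {
    stop("need 0 <= lesion volume <= brain volume", call. = FALSE)
  }
  100 * lesion_cm3 / brain_cm3
}

#' Normalized hemispheric diffusion difference
#'
#' `100 * (D_ipsi - D_contra) / D_avg`: the ipsilesional-minus-contralesional
#' difference in a mean diffusion coefficient, as a percentage of the mean
#' over all tracts pooled across both hemispheres. Antisymmetric under
#' hemisphere swap.
#'
#' @param d_ipsi,d_contra mean coefficient of the ipsi-/contralesional
#'   tracts.
#' @param d_avg mean coefficient over all tracts (non-zero).
#' @return signed percentage.
#' @examples
#' normalized_diff(0.45, 0.5, 0.475)
#' @export
normalized_diff <- function(d_ipsi, d_contra, d_avg) {
  if (any(d_avg == 0)) stop("d_avg must be non-zero", call. = FALSE)
  100 * (d_ipsi - d_contra) / d_avg
}

#' Pearson correlation between tumor load and diffusion change
#'
#' Standard product-moment correlation with a two-sided test, returned as a
#' tidy one-row tibble.
#'
#' @param percent_volumes,normalized_diffs paired numeric vectors (n >= 3).
#' @return tibble with `estimate`, `statistic`, `p.value`, `n`.
#' @export
correlate_volume_diffusion <- function(percent_volumes, normalized_diffs) {
  stopifnot(length(percent_volumes) == length(normalized_diffs),
            length(percent_volumes) >= 3)
  if (stats::sd(percent_volumes) == 0 || stats::sd(normalized_diffs) == 0) {
    stop("zero-variance input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(percent_volumes, normalized_diffs,
                        method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p.value = ct$p.value,
    n = length(percent_volumes)
  )
}
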