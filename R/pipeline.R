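#' Per-streamline mean coefficient values
#'
#' Mean map value over the voxels visited by each streamline (deduplicated
#' within streamline). The natural unit for bundle-level boxplot summaries.
#'
#' @param set a [streamline_set()].
#' @param volume coefficient map.
#' @return numeric vector, one mean per streamline.
#' @export
streamline_mean_values <- function(set, volume) {
  stopifnot(inherits(set, "streamline_set"))
  step <- min(volume$voxel_size_mm) / 2
  vapply(set$points, function(p) {
    lin <- unique(points_to_linear_voxels(densify_polyline(p, step), volume))
    mean(volume$data[lin])
  }, numeric(1))
}

full_grid_mask <- function(volume) {
  mask_volume(array(1, dim(volume$data)), volume$affine)
}

phantom_hemisphere_masks <- function(phantom) {
  ipsi <- phantom$truth$ipsilesional
  list(
    ipsi = if (ipsi == "right") phantom$right_hemisphere_mask else
      phantom$left_hemisphere_mask,
    contra = if (ipsi == "right") phantom$left_hemisphere_mask else
      phantom$right_hemisphere_mask
  )
}

phantom_bundle_mask <- function(phantom, hemisphere) {
  nms <- names(phantom$bundle_masks)
  sel <- grepl(paste0("^", hemisphere, "_"), nms)
  if (!any(sel)) stop("no bundle mask for hemisphere ", hemisphere,
                      call. = FALSE)
  masks <- phantom$bundle_masks[sel]
  if (length(masks) == 1) return(masks[[1]])
  u <- Reduce(`|`, lapply(masks, function(m) m$data != 0))
  mask_volume(array(as.numeric(u), dim(u)), masks[[1]]$affine)
}

#' Analyze one subject
#'
#' Runs the per-subject stages on a phantom (or an equivalent list of
#' volumes, masks and imported tracks): whole-brain tracking, hemispheric
#' and C/I/IE/II streamline selection, tract-voxel value extraction,
#' hemispheric shift functions and downsampled Wilcoxon tests, and the
#' volumetric record. Along-tract profiles need the cohort-level common
#' node count and are assembled by [run_cohort_analysis()].
#'
#' @param phantom a [generate_phantom()] result.
#' @param subject_id subject label.
#' @param tracking a [tracking_params()].
#' @param tracks optional externally tracked [streamline_set()]; skips the
#'   internal tracker.
#' @param shift_seed,wilcoxon_seed seeds for the per-subject statistics.
#' @param wilcoxon_factor downsampling factor for the rank-sum test.
#' @return a `subject_analysis` list (tract values, test tibbles,
#'   volumetric record, selected streamline sets, contralesional means).
#' @export
analyze_subject <- function(phantom, subject_id = "S01",
                            tracking = tracking_params(),
                            tracks = NULL,
                            shift_seed = 1L, wilcoxon_seed = 1L,
                            wilcoxon_factor = 50) {
  stopifnot(inherits(phantom, "phantom"))
  coeffs <- c(fa = "fa", md = "md", ad = "ad", rd = "rd")
  hemis <- phantom_hemisphere_masks(phantom)
  if (is.null(tracks)) {
    tracks <- track(phantom$direction_field, phantom$fa,
                    full_grid_mask(phantom$fa), tracking)
  }
  if (n_streamlines(tracks) == 0) {
    stop("no streamlines for subject ", subject_id, call. = FALSE)
  }
  tracks$meta$subject <- subject_id

  # hemispheric tract groups (whole-brain tracks split by hemisphere)
  sel_ipsi <- select_streamlines(
    tracks, selection_recipe("ipsi", hemis$ipsi, hemis$contra)
  )
  sel_contra <- select_streamlines(
    tracks, selection_recipe("contra", hemis$contra, hemis$ipsi)
  )

  hemi_values <- purrr::map(coeffs, function(cf) {
    list(
      ipsi = extract_tract_values(sel_ipsi, phantom[[cf]],
                                  coefficient = cf)$value,
      contra = extract_tract_values(sel_contra, phantom[[cf]],
                                    coefficient = cf)$value
    )
  })

  shift <- purrr::imap_dfr(hemi_values, function(v, cf) {
    sf <- shift_function(v$ipsi, v$contra, rng_seed = shift_seed)
    dplyr::mutate(tidy(sf), coefficient = cf, subject = subject_id,
                  .before = 1)
  })
  wilcoxon <- purrr::imap_dfr(hemi_values, function(v, cf) {
    dplyr::mutate(
      wilcoxon_downsampled(v$ipsi, v$contra, factor = wilcoxon_factor,
                           rng_seed = wilcoxon_seed),
      coefficient = cf, subject = subject_id, .before = 1
    )
  })

  lesion_cm3 <- lesion_volume(phantom$lesion_mask)
  brain_cm3 <- phantom$truth$brain_volume_cm3
  volumetric <- purrr::imap_dfr(hemi_values, function(v, cf) {
    tibble::tibble(
      subject = subject_id, coefficient = cf,
      lesion_volume_cm3 = lesion_cm3,
      brain_volume_cm3 = brain_cm3,
      percent_tumor_volume = percent_tumor_volume(lesion_cm3, brain_cm3),
      normalized_diff = normalized_diff(
        mean(v$ipsi), mean(v$contra), mean(c(v$ipsi, v$contra))
      )
    )
  })

  # targeted bundle groups
  bundle_ipsi <- phantom_bundle_mask(phantom, phantom$truth$ipsilesional)
  bundle_contra <- phantom_bundle_mask(
    phantom,
    setdiff(c("left", "right"), phantom$truth$ipsilesional)
  )
  lesion <- phantom$lesion_mask
  recipes <- list(
    C = selection_recipe("C", bundle_contra, hemis$ipsi),
    I = selection_recipe("I", bundle_ipsi, hemis$contra),
    IE = selection_recipe("IE", bundle_ipsi, list(hemis$contra, lesion)),
    II = selection_recipe("II", list(bundle_ipsi, lesion), hemis$contra)
  )
  selections <- purrr::map(recipes, function(r) {
    s <- suppressWarnings(select_streamlines(tracks, r))
    s$meta$subject <- rep(subject_id, n_streamlines(s))
    s
  })

  # per-streamline mean FA / MD per group (raw scale)
  group_values <- purrr::map_dfr(c("fa", "md"), function(cf) {
    purrr::imap_dfr(selections, function(s, lab) {
      if (n_streamlines(s) == 0) return(NULL)
      tibble::tibble(
        subject = subject_id, coefficient = cf, group = lab,
        streamline = s$meta$streamline,
        mean_value = streamline_mean_values(s, phantom[[cf]])
      )
    })
  })

  contra_means <- purrr::map(coeffs, function(cf) mean(hemi_values[[cf]]$contra))

  structure(
    list(
      subject = subject_id,
      n_seeds = attr(tracks, "n_seeds"),
      n_tracks = n_streamlines(tracks),
      shift = shift,
      wilcoxon = wilcoxon,
      volumetric = volumetric,
      group_values = group_values,
      selections = selections,
      hemi_values = hemi_values,
      contra_means = contra_means,
      lesion_mask = phantom$lesion_mask,
      midsagittal_axis = phantom$truth$spec$midsagittal_axis,
      maps = list(fa = phantom$fa, md = phantom$md)
    ),
    class = "subject_analysis"
  )
}

#' Run the full cohort analysis
#'
#' Generates (or accepts) one phantom per subject and runs the end-to-end
#' analysis: per-subject hemispheric shift functions and downsampled
#' Wilcoxon tests; volumetric records with the Pearson correlation of
#' percent tumor volume against the normalized hemispheric diffusion
#' difference; Kruskal-Wallis + Dunn comparisons of C/IE/II bundle values
#' (unit configurable: per-subject means by default — streamlines within a
#' subject are pseudoreplicates — or per-streamline means); and pooled
#' along-tract binned profiles with CI-overlap flags (contralesional tracts
#' measured against the flipped lesion). Subjects whose stages fail are
#' excluded with a logged reason, never silently dropped. Fully
#' deterministic given the seeds in the configuration.
#'
#' @param cohort list of [phantom_spec()] (see [phantom_cohort()]) or of
#'   pre-built [generate_phantom()] objects.
#' @param tracking a [tracking_params()].
#' @param fig_unit unit of analysis for the group comparison: `"subject"`,
#'   `"streamline"` or `"voxel"`.
#' @param bin_width_mm along-tract bin width (default 2 mm).
#' @param rng_seed seed for the cohort-level statistics.
#' @param profile_ci unit for the along-tract CIs: `"subject"` (default;
#'   per-subject bin means, the independent unit) or `"pooled"` node values
#'   (narrower, but node values within a subject are not independent).
#' @param verbose print per-subject progress to stderr.
#' @return a `cohort_analysis` list of tibbles: `subjects`, `shift`,
#'   `shift_pooled`, `wilcoxon`, `volumetrics`, `volume_correlation`,
#'   `group_values`, `group_tests`, `profiles`, `overlap_flags`,
#'   `exclusions`, `manifest`.
#' @export
run_cohort_analysis <- function(cohort,
                                tracking = tracking_params(),
                                fig_unit = c("subject", "streamline",
                                             "voxel"),
                                bin_width_mm = 2,
                                rng_seed = 1L,
                                profile_ci = c("subject", "pooled"),
                                verbose = FALSE) {
  fig_unit <- match.arg(fig_unit)
  profile_ci <- match.arg(profile_ci)
  if (inherits(cohort, "phantom_spec") || inherits(cohort, "phantom")) {
    cohort <- list(S01 = cohort)
  }
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(cohort))

  results <- list()
  exclusions <- tibble::tibble(subject = character(), reason = character())
  for (i in seq_along(cohort)) {
    id <- ids[i]
    if (verbose) message("subject ", id)
    res <- tryCatch({
      ph <- cohort[[i]]
      if (inherits(ph, "phantom_spec")) ph <- generate_phantom(ph)
      a <- analyze_subject(
        ph, subject_id = id, tracking = tracking,
        shift_seed = rng_seed + i, wilcoxon_seed = rng_seed + i
      )
      if (n_streamlines(a$selections$II) == 0 ||
          n_streamlines(a$selections$C) == 0) {
        stop("empty bundle selection")
      }
      a
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("excluding subject ", id, ": ", res)
      exclusions <- dplyr::bind_rows(
        exclusions, tibble::tibble(subject = id, reason = res)
      )
    } else {
      results[[id]] <- res
    }
  }
  if (length(results) == 0) stop("all subjects excluded", call. = FALSE)

  subjects <- purrr::map_dfr(results, function(r) {
    tibble::tibble(subject = r$subject, n_seeds = r$n_seeds,
                   n_tracks = r$n_tracks)
  })
  shift <- purrr::map_dfr(results, "shift")
  wilcoxon <- purrr::map_dfr(results, "wilcoxon")
  volumetrics <- purrr::map_dfr(results, "volumetric")

  # cohort-pooled shift function per coefficient (all subjects' voxels)
  shift_pooled <- purrr::map_dfr(c("fa", "md", "ad", "rd"), function(cf) {
    ip <- unlist(purrr::map(results, function(r) r$hemi_values[[cf]]$ipsi))
    co <- unlist(purrr::map(results, function(r) r$hemi_values[[cf]]$contra))
    dplyr::mutate(tidy(shift_function(ip, co, rng_seed = rng_seed)),
                  coefficient = cf, .before = 1)
  })

  volume_correlation <- volumetrics |>
    dplyr::group_by(.data$coefficient) |>
    dplyr::group_modify(function(d, key) {
      # undefined for tiny or degenerate cohorts; report NA rather than fail
      tryCatch(
        correlate_volume_diffusion(d$percent_tumor_volume,
                                   d$normalized_diff),
        error = function(e) {
          tibble::tibble(estimate = NA_real_, statistic = NA_real_,
                         p.value = NA_real_, n = nrow(d))
        }
      )
    }) |>
    dplyr::ungroup()

  # targeted bundle comparison (C vs IE vs II), min-max normalized per
  # subject and coefficient across groups jointly
  group_values <- purrr::map_dfr(results, "group_values") |>
    dplyr::filter(.data$group %in% c("C", "IE", "II")) |>
    dplyr::group_by(.data$subject, .data$coefficient) |>
    dplyr::mutate(normalized = minmax_normalize(.data$mean_value)) |>
    dplyr::ungroup()

  test_input <- if (fig_unit == "subject") {
    group_values |>
      dplyr::group_by(.data$coefficient, .data$subject, .data$group) |>
      dplyr::summarise(value = mean(.data$normalized), .groups = "drop")
  } else if (fig_unit == "streamline") {
    dplyr::transmute(group_values, coefficient = .data$coefficient,
                     subject = .data$subject, group = .data$group,
                     value = .data$normalized)
  } else {
    purrr::map_dfr(results, function(r) {
      purrr::map_dfr(c("fa", "md"), function(cf) {
        purrr::imap_dfr(r$selections[c("C", "IE", "II")], function(s, lab) {
          v <- extract_tract_values(s, r$maps[[cf]])$value
          tibble::tibble(coefficient = cf, subject = r$subject,
                         group = lab, value = v)
        })
      })
    }) |>
      dplyr::group_by(.data$subject, .data$coefficient) |>
      dplyr::mutate(value = minmax_normalize(.data$value)) |>
      dplyr::ungroup()
  }
  group_tests <- purrr::map(
    stats::setNames(c("fa", "md"), c("fa", "md")),
    function(cf) {
      d <- dplyr::filter(test_input, .data$coefficient == cf)
      dunn_posthoc(d$value, d$group)
    }
  )

  # along-tract analysis: common node count per group across subjects,
  # normalization to the contralesional hemisphere mean, flipped lesion for
  # the contralesional control
  n_nodes <- purrr::map(
    stats::setNames(c("C", "IE", "II"), c("C", "IE", "II")),
    function(g) {
      common_node_count(purrr::map(results, function(r) r$selections[[g]]))
    }
  )
  profiles_raw <- purrr::map_dfr(c("fa", "md"), function(cf) {
    purrr::map_dfr(results, function(r) {
      flipped <- flip_lesion(r$lesion_mask, r$midsagittal_axis)
      purrr::map_dfr(c("C", "IE", "II"), function(g) {
        s <- r$selections[[g]]
        if (n_streamlines(s) == 0) return(NULL)
        lesion <- if (g == "C") flipped else r$lesion_mask
        dplyr::mutate(
          tract_distance_profile(
            s, r$maps[[cf]], lesion, n_nodes[[g]],
            contralesional_mean = r$contra_means[[cf]]
          ),
          coefficient = cf, .before = 1
        )
      })
    })
  })
  profiles <- profiles_raw |>
    dplyr::group_by(.data$coefficient) |>
    dplyr::group_modify(function(d, key) {
      if (profile_ci == "subject") {
        bw <- bin_width_mm
        lo <- floor(min(d$distance_mm) / bw) * bw
        d <- d |>
          dplyr::mutate(bin = lo + bw * floor((.data$distance_mm - lo) / bw) +
                          bw / 2) |>
          dplyr::group_by(.data$subject, .data$group, .data$bin) |>
          dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
          dplyr::transmute(group = .data$group,
                           distance_mm = .data$bin, value = .data$value)
      }
      binned_profile(d, bin_width_mm = bin_width_mm)
    }) |>
    dplyr::ungroup()
  overlap_flags <- purrr::map_dfr(c("fa", "md"), function(cf) {
    b <- dplyr::filter(profiles, .data$coefficient == cf)
    class(b) <- c("binned_profile", class(b))
    purrr::map_dfr(list(c("II", "C"), c("IE", "C"), c("II", "IE")),
                   function(pair) {
                     dplyr::mutate(ci_overlap_flags(b, pair),
                                   coefficient = cf, .before = 1)
                   })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("tractshift")),
    rng_seed = rng_seed,
    tracking = unclass(tracking),
    fig_unit = fig_unit,
    bin_width_mm = bin_width_mm,
    profile_ci = profile_ci,
    n_nodes = n_nodes,
    subjects = ids,
    excluded = exclusions$subject
  )

  structure(
    list(
      subjects = subjects, shift = shift, shift_pooled = shift_pooled,
      wilcoxon = wilcoxon, volumetrics = volumetrics,
      volume_correlation = volume_correlation,
      group_values = group_values, group_tests = group_tests,
      profiles = profiles, overlap_flags = overlap_flags,
      exclusions = exclusions, manifest = manifest
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects (%d excluded)\n",
              nrow(x$subjects), nrow(x$exclusions)))
  cat("Kruskal-Wallis + Dunn (per-", x$manifest$fig_unit, " values):\n",
      sep = "")
  for (cf in names(x$group_tests)) {
    cat(" ", toupper(cf), ": ")
    gt <- x$group_tests[[cf]]
    cat(sprintf("H(%d) = %.2f, p = %.3g\n", gt$omnibus$df, gt$omnibus$H,
                gt$omnibus$p.value))
  }
  invisible(x)
}

#' Write cohort analysis tables
#'
#' Writes every result table as TSV plus a JSON manifest (seeds, parameters,
#' package version) into a directory; byte-identical across reruns of the
#' same configuration.
#'
#' @param analysis a [run_cohort_analysis()] result.
#' @param directory output directory.
#' @return the directory, invisibly.
#' @export
write_analysis <- function(analysis, directory) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("subjects", "shift", "shift_pooled", "wilcoxon", "volumetrics",
            "volume_correlation", "group_values", "profiles",
            "overlap_flags", "exclusions")
  for (tb in tabs) {
    utils::write.table(
      analysis[[tb]], file.path(directory, paste0(tb, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  gt <- purrr::imap_dfr(analysis$group_tests, function(g, cf) {
    dplyr::mutate(g$pairwise, coefficient = cf,
                  H = g$omnibus$H, omnibus_p = g$omnibus$p.value,
                  .before = 1)
  })
  utils::write.table(gt, file.path(directory, "group_tests.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(analysis$manifest,
                       file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}
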