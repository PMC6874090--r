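#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a shift function
#'
#' Decile differences against the first group's deciles, with the bootstrap
#' confidence band; significant deciles (interval excluding zero) are
#' filled.
#'
#' @param object a [shift_function()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.shift_function <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$est1, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "black")) +
    ggplot2::labs(x = "group 1 decile", y = "decile difference (1 - 2)",
                  fill = "CI excludes 0")
}

#' Plot a mirrored density comparison
#'
#' Group 1 above the axis, group 2 mirrored below, with median markers.
#'
#' @param object a [mirrored_density_summary()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mirrored_density <- function(object, ...) {
  med <- attr(object, "medians")
  d <- dplyr::mutate(
    tibble::as_tibble(object),
    density = ifelse(.data$group == "2", -.data$density, .data$density)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$density,
                                  fill = .data$group)) +
    ggplot2::geom_area(position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = med, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "value", y = "density (group 2 mirrored)")
}

#' Plot binned along-tract profiles
#'
#' Group means by signed distance from the lesion boundary with 95%
#' confidence ribbons; negative distances are inside the lesion.
#'
#' @param object a [binned_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binned_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center_mm,
                                       y = .data$mean,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from lesion boundary (mm)",
                  y = "normalized coefficient")
}
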