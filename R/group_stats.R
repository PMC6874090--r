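#' Kruskal-Wallis omnibus test across selection groups
#'
#' Rank-based H test with tie correction (via [stats::kruskal.test()]),
#' returned as a tidy one-row tibble.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`; or pass a list of
#'   numeric vectors as `values` and omit `groups`.
#' @return tibble with `H`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (stats::var(values) == 0) {
    return(tibble::tibble(H = 0, df = nlevels(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = kt$p.value
  )
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from pooled-rank mean differences with
#' tie-corrected variance, gated on the Kruskal-Wallis omnibus: pairwise
#' p-values are only reported when the omnibus p is below
#' `only_if_omnibus_p_below` (otherwise the tibble carries the z values with
#' `gated = TRUE`). P-value adjustment across pairs is configurable via
#' [stats::p.adjust()] methods (default `"none"`).
#'
#' @inheritParams kruskal_wallis
#' @param only_if_omnibus_p_below omnibus significance gate (default 0.05).
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return a `group_test` object: list with `omnibus` (tibble) and
#'   `pairwise` (tibble: `group1`, `group2`, `z`, `p.value`, `p.adjusted`,
#'   `gated`).
#' @export
dunn_posthoc <- function(values, groups = NULL,
                         only_if_omnibus_p_below = 0.05,
                         p_adjust = "none") {
  if (is.list(values) && is.null(groups)) {
    nms <- names(values)
    if (is.null(nms)) nms <- as.character(seq_along(values))
    groups <- rep(nms, lengths(values))
    values <- unlist(values)
  }
  groups <- factor(groups)
  omnibus <- kruskal_wallis(values, groups)
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(rk, groups, mean)
  sizes <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se2 <- (n * (n + 1) / 12 - tie_corr) * (1 / sizes[[i]] + 1 / sizes[[j]])
    z[k] <- if (se2 > 0) (rbar[[i]] - rbar[[j]]) / sqrt(se2) else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  gated <- omnibus$p.value >= only_if_omnibus_p_below
  pairwise <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z,
    p.value = if (gated) NA_real_ else p,
    p.adjusted = if (gated) NA_real_ else stats::p.adjust(p, p_adjust),
    gated = gated
  )
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H(%d) = %.3f, p = %.3g\n",
              x$omnibus$df, x$omnibus$H, x$omnibus$p.value))
  if (all(x$pairwise$gated)) {
    cat("omnibus not significant; pairwise p-values withheld\n")
  } else {
    print(x$pairwise)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname dunn_posthoc
#' @param x a `group_test`.
#' @param ... unused.
#' @export
tidy.group_test <- function(x, ...) x$pairwise

#' @rdname dunn_posthoc
#' @export
glance.group_test <- function(x, ...) x$omnibus

#' @rdname shift_function
#' @param x a `shift_function`.
#' @param ... unused.
#' @export
tidy.shift_function <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname shift_function
#' @export
glance.shift_function <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n1 = cfg$n1, n2 = cfg$n2,
    n_iterations = cfg$n_iterations,
    n_significant = sum(x$significant),
    max_abs_difference = max(abs(x$difference))
  )
}
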