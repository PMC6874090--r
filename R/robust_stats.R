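#' Harrell-Davis quantile estimator
#'
#' Estimates the q-th quantile as a weighted sum of all order statistics,
#' with weights from the regularized incomplete beta function:
#' `w_i = I(i/n; a, b) - I((i-1)/n; a, b)` where `a = (n+1) q` and
#' `b = (n+1)(1-q)`. The weights sum to one, so the estimator is bounded by
#' the sample range and is location-scale equivariant.
#'
#' @param sample numeric vector (n >= 2).
#' @param q quantile level(s) in (0, 1); vectorized.
#' @return numeric vector of quantile estimates, one per `q`.
#' @examples
#' harrell_davis(1:9, 0.5)
#' @export
harrell_davis <- function(sample, q) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 2) stop("need a sample of size >= 2", call. = FALSE)
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)", call. = FALSE)
  xs <- sort(sample)
  w <- hd_weights(n, q)
  as.vector(w %*% xs)
}

# length(q) x n matrix of Harrell-Davis weights
hd_weights <- function(n, q) {
  grid <- seq_len(n) / n
  t(vapply(q, function(qq) {
    a <- (n + 1) * qq
    b <- (n + 1) * (1 - qq)
    diff(c(0, stats::pbeta(grid, a, b)))
  }, numeric(n)))
}

#' Decile shift function with bootstrap confidence intervals
#'
#' Compares two distributions at the deciles q = 0.1, ..., 0.9 estimated
#' with the Harrell-Davis estimator. The per-decile difference is
#' `est1 - est2`; its standard error is estimated by bootstrap (default: 100
#' iterations of 200 observations drawn with replacement from each group),
#' and the confidence interval is `difference +/- t * SE` with the t
#' critical value at the bootstrap degrees of freedom. A bootstrap at a
#' resample size m estimates the sampling variance of an m-observation
#' statistic, so when `samples_per_iteration` differs from the group size n
#' each group's bootstrap variance is rescaled by `m / n`; set
#' `samples_per_iteration = NULL` to resample at full size. A decile is
#' flagged significant when its interval excludes zero — jointly across the
#' nine deciles this bounds the familywise error via the simultaneous
#' bootstrap bands.
#'
#' @param sample1,sample2 numeric vectors (a warning is issued below 20
#'   values; decile estimates are unstable there).
#' @param n_iterations bootstrap iterations (default 100).
#' @param samples_per_iteration resample size per iteration (default 200);
#'   `NULL` = resample each group at its own size.
#' @param rng_seed integer seed.
#' @param ci_level confidence level (default 0.95).
#' @param ci `"normal"` (z x bootstrap SE, default) or `"percentile"`.
#' @return a `shift_function` tibble: `decile`, `est1`, `est2`,
#'   `difference`, `se`, `ci_low`, `ci_high`, `significant`.
#' @export
shift_function <- function(sample1, sample2,
                           n_iterations = 100,
                           samples_per_iteration = 200,
                           rng_seed = 0L,
                           ci_level = 0.95,
                           ci = c("normal", "percentile")) {
  ci <- match.arg(ci)
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  if (length(sample1) < 20 || length(sample2) < 20) {
    warning("fewer than 20 values in a group; decile estimates are unstable")
  }
  q <- seq(0.1, 0.9, by = 0.1)
  est1 <- harrell_davis(sample1, q)
  est2 <- harrell_davis(sample2, q)
  diff_hat <- est1 - est2

  set.seed(rng_seed)
  boot_one <- function(x, m) {
    w <- hd_weights(m, q)
    vapply(seq_len(n_iterations), function(i) {
      as.vector(w %*% sort(x[sample.int(length(x), m, replace = TRUE)]))
    }, numeric(length(q)))
  }
  m1 <- if (is.null(samples_per_iteration)) length(sample1) else
    samples_per_iteration
  m2 <- if (is.null(samples_per_iteration)) length(sample2) else
    samples_per_iteration
  b1 <- boot_one(sample1, m1) # 9 x n_iterations
  b2 <- boot_one(sample2, m2)
  # the groups are independent: the SE of the difference is the root of the
  # summed per-group bootstrap variances, each rescaled from the resample
  # size m to the group's n (variance of an m-out-of-n statistic ~ 1/m)
  v1 <- apply(b1, 1, stats::var) * m1 / length(sample1)
  v2 <- apply(b2, 1, stats::var) * m2 / length(sample2)
  se <- sqrt(v1 + v2)
  alpha <- 1 - ci_level
  if (ci == "normal") {
    # t critical value with the bootstrap degrees of freedom: the SE is
    # itself estimated from n_iterations replicates per group
    crit <- stats::qt(1 - alpha / 2, 2 * (n_iterations - 1))
    lo <- diff_hat - crit * se
    hi <- diff_hat + crit * se
  } else {
    bdiff <- (b1 - rowMeans(b1)) * sqrt(m1 / length(sample1)) -
      (b2 - rowMeans(b2)) * sqrt(m2 / length(sample2))
    qs <- apply(diff_hat + bdiff, 1, stats::quantile,
                probs = c(alpha / 2, 1 - alpha / 2))
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  out <- tibble::tibble(
    decile = q, est1 = est1, est2 = est2, difference = diff_hat,
    se = se, ci_low = lo, ci_high = hi,
    significant = lo > 0 | hi < 0
  )
  class(out) <- c("shift_function", class(out))
  attr(out, "config") <- list(
    n_iterations = n_iterations, samples_per_iteration = samples_per_iteration,
    rng_seed = rng_seed, ci_level = ci_level, ci = ci,
    n1 = length(sample1), n2 = length(sample2)
  )
  out
}

#' Downsampled two-sample Wilcoxon rank-sum test
#'
#' Voxelwise tract distributions are massively autocorrelated, so the test
#' is run on a random subsample: each group is reduced to `floor(n/factor)`
#' values by uniform subsampling without replacement (seeded), then a
#' two-sided rank-sum test with normal approximation and tie correction is
#' applied. The sign convention is Z > 0 when `sample1` is stochastically
#' larger than `sample2`.
#'
#' @param sample1,sample2 numeric vectors with at least `factor` values.
#' @param factor downsampling factor (default 50).
#' @param rng_seed integer seed for the subsampling.
#' @return tibble with `z`, `p`, `n1`, `n2` (reduced sizes).
#' @export
wilcoxon_downsampled <- function(sample1, sample2, factor = 50,
                                 rng_seed = 0L) {
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  if (length(sample1) < factor || length(sample2) < factor) {
    stop("each sample needs at least `factor` values", call. = FALSE)
  }
  m1 <- floor(length(sample1) / factor)
  m2 <- floor(length(sample2) / factor)
  # each sample is subsampled from the same seeded stream, so swapping the
  # arguments selects the same subsets and exactly negates Z
  set.seed(rng_seed)
  x <- sample1[sample.int(length(sample1), m1)]
  set.seed(rng_seed)
  y <- sample2[sample.int(length(sample2), m2)]
  if (m1 < 5 || m2 < 5) {
    warning("fewer than 5 values after downsampling; ",
            "normal approximation is poor")
  }
  rk <- rank(c(x, y))
  n <- m1 + m2
  w <- sum(rk[seq_len(m1)])
  mu <- m1 * (n + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- m1 * m2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  tibble::tibble(z = z, p = p, n1 = m1, n2 = m2)
}

#' Mirrored density summary of two samples
#'
#' Kernel density estimates of both samples on a common grid, plus medians —
#' the plot-ready ingredients of a mirrored (violin-style) distribution
#' comparison. Each density integrates to 1.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @param n grid size for the density estimate.
#' @return a `mirrored_density` tibble: `value`, `density`, `group`
#'   (`"1"`/`"2"`); attribute `medians`.
#' @export
mirrored_density_summary <- function(sample1, sample2, n = 512) {
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  stopifnot(length(sample1) > 1, length(sample2) > 1)
  rng <- range(c(sample1, sample2))
  pad <- diff(rng) * 0.1 + 1e-12
  d1 <- stats::density(sample1, n = n, from = rng[1] - pad, to = rng[2] + pad)
  d2 <- stats::density(sample2, n = n, from = rng[1] - pad, to = rng[2] + pad)
  out <- tibble::tibble(
    value = c(d1$x, d2$x),
    density = c(d1$y, d2$y),
    group = rep(c("1", "2"), each = n)
  )
  attr(out, "medians") <- c(stats::median(sample1), stats::median(sample2))
  class(out) <- c("mirrored_density", class(out))
  out
}
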