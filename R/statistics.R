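#' Summarize a delta population
#'
#' Mean, sample SD (n-1 denominator) and a histogram of a per-pixel or
#' per-cell delta population, following the mean +/- SD reporting
#' convention for population enrichment. Invalid (`NA`) values are dropped
#' first; an empty population after filtering is an error naming the class
#' and basis.
#'
#' @param values Numeric delta values in per mil.
#' @param class Population label (e.g. `"heterotroph"`), recorded in the
#'   result.
#' @param basis `"pixel"` or `"cell"`.
#' @param bins Number of histogram bins (default 50).
#' @param range Optional histogram range `c(low, high)`; defaults to the
#'   data range.
#' @return An object of class `nanosip_popsummary`: list with `summary`
#'   (one-row tibble: `class`, `basis`, `n`, `mean`, `sd`, `single_value`)
#'   and `histogram` (tibble: `bin_low`, `bin_high`, `bin_mid`, `count`).
#' @export
summarize_population <- function(values, class = "population",
                                 basis = c("pixel", "cell"), bins = 50,
                                 range = NULL) {
  basis <- match.arg(basis)
  v <- values[is.finite(values)]
  if (!length(v))
    stop(sprintf("empty population: no valid %s-basis values for class %s",
                 basis, class), call. = FALSE)
  single <- length(v) == 1L
  if (is.null(range)) range <- base::range(v)
  if (range[1] == range[2]) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  cnt <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                            1L), bins), nbins = bins)
  structure(list(
    summary = tibble::tibble(
      class = class, basis = basis, n = length(v),
      mean = mean(v), sd = if (single) 0 else stats::sd(v),
      single_value = single),
    histogram = tibble::tibble(
      bin_low = edges[-(bins + 1L)], bin_high = edges[-1L],
      bin_mid = (edges[-1L] + edges[-(bins + 1L)]) / 2, count = cnt)),
    class = "nanosip_popsummary")
}

#' @export
print.nanosip_popsummary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s (%s basis): n = %d, mean = %.2f permil, SD = %.2f permil\n",
              s$class, s$basis, s$n, s$mean, s$sd))
  invisible(x)
}

#' @export
glance.nanosip_popsummary <- function(x, ...) x$summary

#' @export
tidy.nanosip_popsummary <- function(x, ...) x$histogram

#' Two-sample rank test between delta populations
#'
#' Compares two enrichment populations with a Wilcoxon-family rank test.
#' The default (and generally appropriate) variant for independent pixel or
#' cell populations is the unpaired rank-sum test; the paired signed-rank
#' variant is available for genuinely paired designs and requires equal
#' lengths. P values are exact (by enumeration) for combined n <= 25
#' without ties, otherwise a normal approximation with tie correction is
#' used. A degenerate paired comparison with all zero differences reports
#' p = 1 by convention. A p value below 1e-3 is formatted as "p < 1e-3",
#' never as a literal zero.
#'
#' @param a,b Numeric delta values (per mil); `NA` dropped.
#' @param variant `"rank_sum"` (unpaired, default) or `"signed_rank"`
#'   (paired).
#' @return An object of class `nanosip_ranktest`: list with `statistic_W`,
#'   `p_value`, `variant`, `n1`, `n2`, `exact`.
#' @export
compare_populations <- function(a, b, variant = c("rank_sum", "signed_rank")) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("both populations must be non-empty", call. = FALSE)
  if (variant == "signed_rank" && length(a) != length(b))
    stop("signed_rank is a paired test and requires equal lengths; ",
         "use variant = \"rank_sum\" for independent populations",
         call. = FALSE)
  exact <- (length(a) + length(b)) <= 25
  if (variant == "signed_rank" && all(a == b)) {
    res <- list(statistic = c(V = 0), p.value = 1)
  } else {
    res <- suppressWarnings(stats::wilcox.test(
      a, b, paired = variant == "signed_rank",
      exact = exact, correct = TRUE))
    exact <- exact && !any(duplicated(c(a, b)))
  }
  structure(list(
    statistic_W = unname(res$statistic), p_value = res$p.value,
    variant = if (variant == "rank_sum") "rank_sum_unpaired"
              else "signed_rank_paired",
    n1 = length(a), n2 = length(b), exact = exact),
    class = "nanosip_ranktest")
}

#' Format a p value, reporting very small values as a bound
#' @param p A p value.
#' @return Character, e.g. `"0.031"` or `"< 1e-3"`.
#' @export
format_p <- function(p) {
  if (p < 1e-3) "< 1e-3" else sprintf("%.3g", p)
}

#' @export
print.nanosip_ranktest <- function(x, ...) {
  cat(sprintf("Wilcoxon %s: W = %g, p %s (n1 = %d, n2 = %d, %s)\n",
              x$variant, x$statistic_W,
              if (x$p_value < 1e-3) format_p(x$p_value)
              else paste("=", format_p(x$p_value)),
              x$n1, x$n2,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' @export
tidy.nanosip_ranktest <- function(x, ...) {
  tibble::tibble(statistic_W = x$statistic_W, p_value = x$p_value,
                 variant = x$variant, n1 = x$n1, n2 = x$n2,
                 exact = x$exact)
}

#' @export
glance.nanosip_ranktest <- tidy.nanosip_ranktest

#' 95% confidence ellipse of a bivariate delta cloud
#'
#' Fits the mean and covariance of (delta13C, delta15N) points and returns
#' the ellipse containing 95% of a bivariate normal with those moments:
#' semi-axes are the square roots of the covariance eigenvalues scaled by
#' the 0.95 chi-square quantile with 2 degrees of freedom.
#'
#' @param points Two-column matrix or data frame of (delta13C, delta15N).
#' @param coverage Coverage probability (fixed default 0.95).
#' @return An object of class `nanosip_ellipse`: `center`, `semi_axes`
#'   (major, minor), `angle` (radians, major axis vs x), `coverage`, `cov`.
#' @export
ellipse_95 <- function(points, coverage = 0.95) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3)
    stop("need at least 3 points for a confidence ellipse", call. = FALSE)
  S <- stats::cov(pts)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= .Machine$double.eps * max(e$values[1], 1))
    stop("degenerate covariance: points are collinear", call. = FALSE)
  k <- stats::qchisq(coverage, df = 2)
  structure(list(
    center = colMeans(pts),
    semi_axes = sqrt(k * e$values),
    angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
    coverage = coverage, cov = S, n = nrow(pts)),
    class = "nanosip_ellipse")
}

#' @export
print.nanosip_ellipse <- function(x, ...) {
  cat(sprintf("%.0f%% ellipse: center (%.1f, %.1f), semi-axes (%.1f, %.1f), angle %.1f deg\n",
              100 * x$coverage, x$center[1], x$center[2],
              x$semi_axes[1], x$semi_axes[2], x$angle * 180 / pi))
  invisible(x)
}

#' Points on the boundary of a fitted ellipse
#' @param ellipse A `nanosip_ellipse`.
#' @param n Number of boundary points.
#' @return A tibble with `x`, `y`.
#' @export
ellipse_boundary <- function(ellipse, n = 100) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- rbind(ellipse$semi_axes[1] * cos(t), ellipse$semi_axes[2] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  xy <- t(rot %*% u + ellipse$center)
  tibble::tibble(x = xy[, 1], y = xy[, 2])
}

#' Test whether points fall inside a fitted ellipse
#' @param ellipse A `nanosip_ellipse`.
#' @param points Two-column matrix of points.
#' @return Logical vector (Mahalanobis distance within the coverage
#'   quantile).
#' @export
in_ellipse <- function(ellipse, points) {
  pts <- as.matrix(points)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$cov)
  d2 <= stats::qchisq(ellipse$coverage, df = 2)
}

#' Mean replicate enrichment signature
#'
#' Averages per-image delta histograms across replicate images: per-bin
#' mean and SD of counts, with the shared bin edges. All histograms must
#' share identical bins.
#'
#' @param histograms List of histogram tibbles as produced by
#'   [summarize_population()] (`bin_low`, `bin_high`, `count` columns).
#' @return A tibble: `bin_low`, `bin_high`, `bin_mid`, `mean_count`,
#'   `sd_count`, `n_replicates`.
#' @export
replicate_signature <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  ref <- histograms[[1]]
  for (h in histograms[-1]) {
    if (!isTRUE(all.equal(h$bin_low, ref$bin_low)) ||
        !isTRUE(all.equal(h$bin_high, ref$bin_high)))
      stop("replicate histograms have mismatched bins", call. = FALSE)
  }
  counts <- vapply(histograms, function(h) as.double(h$count),
                   double(nrow(ref)))
  counts <- matrix(counts, nrow = nrow(ref))
  tibble::tibble(
    bin_low = ref$bin_low, bin_high = ref$bin_high,
    bin_mid = (ref$bin_low + ref$bin_high) / 2,
    mean_count = rowMeans(counts),
    sd_count = apply(counts, 1, stats::sd),
    n_replicates = length(histograms))
}
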