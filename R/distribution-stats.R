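# Summaries of feature-size arrays: quantiles (linear interpolation,
# "type 7"), moments, Tukey boxplot statistics, and Gaussian KDE on the
# log10 axis.

#' Linear-interpolation quantile
#'
#' The quantile at position 1 + q(n-1) on the sorted sample, linearly
#' interpolated between order statistics (the common "type 7" definition).
#'
#' @param values Non-empty numeric vector.
#' @param q Probabilities, each strictly inside (0, 1).
#' @return Numeric vector of quantiles, unnamed.
#' @export
quantile_linear <- function(values, q) {
  if (length(values) == 0L) stop("empty values")
  if (anyNA(values)) stop("values contain NA")
  if (length(q) == 0L || any(q <= 0 | q >= 1)) stop("q must lie in (0, 1)")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Summarize a feature-size distribution
#'
#' Mean, sample standard deviation (n - 1 denominator), median, quartiles,
#' IQR and arbitrary extra quantiles of a size array.
#'
#' @param values Non-empty numeric vector.
#' @param qs Quantiles to report in addition to the quartiles.
#' @return Object of class `size_summary` with fields `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75`, `iqr`, `quantiles` (named by probability) and
#'   `sd_flagged` (TRUE for a single observation, where sd is reported as
#'   0).
#' @export
summarize_sizes <- function(values,
                            qs = c(0.01, 0.05, 0.10, 0.25, 0.75, 0.80, 0.90, 0.99)) {
  if (length(values) == 0L) stop("empty values")
  if (anyNA(values)) stop("values contain NA")
  sd_flag <- length(values) == 1L
  qv <- quantile_linear(values, qs)
  qq <- quantile_linear(values, c(0.25, 0.5, 0.75))
  structure(list(n = length(values),
                 mean = mean(values),
                 sd = if (sd_flag) 0 else stats::sd(values),
                 median = qq[2], q25 = qq[1], q75 = qq[3],
                 iqr = qq[3] - qq[1],
                 quantiles = stats::setNames(qv, qs),
                 sd_flagged = sd_flag),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("size_summary: n = %d, mean = %.2f, sd = %.2f%s\n",
              x$n, x$mean, x$sd, if (x$sd_flagged) " (single value)" else ""))
  cat(sprintf("  median = %.2f, IQR = %.2f [q25 = %.2f, q75 = %.2f]\n",
              x$median, x$iqr, x$q25, x$q75))
  cat("  quantiles:", paste(sprintf("%s: %.4g", names(x$quantiles), x$quantiles),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian kernel density estimate on the log10 axis
#'
#' Evaluates a Gaussian KDE of log10-transformed sizes on a uniform grid of
#' `gridsize` points spanning the data range extended by three bandwidths on
#' each side.  The density is normalized on the log10 axis.  By default the
#' bandwidth is the absolute kernel standard deviation in log10 units; with
#' `bw_mode = "scott-factor"` it instead scales Scott's rule-of-thumb
#' bandwidth (sd * n^(-1/5)), mirroring plotting libraries that treat the
#' bandwidth argument as a factor.
#'
#' @param values Positive sizes in bp.
#' @param bandwidth Positive bandwidth (log10 units, or a unitless factor
#'   under `"scott-factor"`).
#' @param gridsize Number of grid points (at least 16).
#' @param bw_mode `"absolute"` or `"scott-factor"`.
#' @return Object of class `kde_curve` with `grid`, `density`, `bandwidth`
#'   (the absolute value used) and `gridsize`.
#' @export
kde_log10 <- function(values, bandwidth, gridsize,
                      bw_mode = c("absolute", "scott-factor")) {
  bw_mode <- match.arg(bw_mode)
  if (length(values) == 0L) stop("empty values")
  if (any(values <= 0)) stop("all values must be positive to take log10")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (gridsize < 16L) stop("gridsize must be at least 16")
  lv <- log10(values)
  bw <- if (bw_mode == "absolute") bandwidth
        else {
          s <- stats::sd(lv)
          if (is.na(s) || s == 0) s <- 1e-3
          bandwidth * s * length(lv)^(-1/5)
        }
  d <- stats::density(lv, bw = bw, kernel = "gaussian", n = gridsize,
                      from = min(lv) - 3 * bw, to = max(lv) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw,
                 gridsize = as.integer(gridsize)),
            class = "kde_curve")
}

#' @export
print.kde_curve <- function(x, ...) {
  cat(sprintf("kde_curve: %d grid points on [%.3f, %.3f] log10(bp), bw = %.4g\n",
              x$gridsize, min(x$grid), max(x$grid), x$bandwidth))
  invisible(x)
}

#' Tukey boxplot statistics
#'
#' Median and type-7 quartiles with whiskers at the most extreme data
#' points inside the Tukey fences (quartiles +/- 1.5 IQR); points outside
#' the fences are outliers.
#'
#' @param values Non-empty numeric vector.
#' @return Object of class `boxplot_stats` with `median`, `q25`, `q75`,
#'   `whisker_low`, `whisker_high` and `outliers`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop("empty values")
  if (anyNA(values)) stop("values contain NA")
  qq <- quantile_linear(values, c(0.25, 0.5, 0.75))
  iqr <- qq[3] - qq[1]
  lo_fence <- qq[1] - 1.5 * iqr
  hi_fence <- qq[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = qq[2], q25 = qq[1], q75 = qq[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside])),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("boxplot_stats: median %.3g [q25 %.3g, q75 %.3g], whiskers [%.3g, %.3g], %d outliers\n",
              x$median, x$q25, x$q75, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}
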