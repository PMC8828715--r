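# First-order intensity statistics over the ROI voxel multiset.

# 19 first-order statistics of a numeric vector. Entropy and uniformity use a
# fixed-count equal-width histogram over the vector's own range; a zero-range
# (constant) input has entropy 0 and uniformity 1.
first_order_values <- function(x, n_bins = 32L, prefix = "fo") {
  n <- length(x)
  mu <- mean(x)
  med <- stats::median(x)
  v <- stats::var(x) * (n - 1) / n     # population variance
  if (!is.finite(v)) v <- 0
  s <- sqrt(v)
  cm3 <- mean((x - mu)^3)
  cm4 <- mean((x - mu)^4)
  skew <- if (s > 0) cm3 / s^3 else 0
  kurt <- if (s > 0) cm4 / s^4 - 3 else 0
  rng <- range(x)
  if (diff(rng) > 0) {
    b <- pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    p <- tabulate(b, n_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
    uniformity <- sum(p^2)
  } else {
    entropy <- 0
    uniformity <- 1
  }
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  core <- x[x >= qs[1] & x <= qs[4]]
  rmad <- if (length(core)) mean(abs(core - mean(core))) else 0
  vals <- c(
    mean = mu, median = med, min = rng[1], max = rng[2],
    range = diff(rng), variance = v, sd = s,
    mad_median = stats::median(abs(x - med)),
    skewness = skew, kurtosis = kurt,
    energy = sum(x^2), rms = sqrt(mean(x^2)),
    entropy = entropy, uniformity = uniformity,
    p10 = qs[1], p90 = qs[4], iqr = qs[3] - qs[2],
    rmad = rmad,
    cov = if (mu != 0) s / mu else 0
  )
  names(vals) <- paste(prefix, names(vals), sep = ".")
  vals
}

#' First-order intensity features of a tumour ROI
#'
#' Computes 19 statistics of the ROI intensity multiset: mean, median, min,
#' max, range, variance, standard deviation, median absolute deviation about
#' the median, skewness, excess kurtosis, energy, root mean square, fixed-bin
#' histogram entropy, uniformity, 10th/90th percentiles, interquartile range,
#' robust mean absolute deviation (within the 10th-90th percentile band) and
#' coefficient of variation.
#'
#' @param vm A [volume_mask()].
#' @param n_bins Histogram bin count for entropy/uniformity.
#' @return Named numeric vector of length 19 (names prefixed `fo.`), with
#'   attribute `block = "HC"`.
#' @export
first_order <- function(vm, n_bins = 32L) {
  stopifnot(inherits(vm, "volume_mask"))
  x <- vm$intensities[vm$mask]
  if (!length(x)) stop("mask is empty", call. = FALSE)
  structure(first_order_values(x, n_bins), block = "HC")
}
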