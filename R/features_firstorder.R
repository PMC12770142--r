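#' First-order intensity statistics
#'
#' The 18 standard first-order radiomic features over the masked voxels:
#' Mean, Median, Minimum, Maximum, Range, Variance (population), Skewness,
#' Kurtosis (Pearson, not excess), Energy, TotalEnergy (energy times voxel
#' volume), Entropy and Uniformity (over the discretized grey-level
#' histogram, base-2 log), MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation (mean absolute deviation of values inside
#' the \[P10, P90\] interval from their own mean), RootMeanSquared,
#' 10Percentile, 90Percentile and InterquartileRange (linear-interpolation
#' quantiles). Skewness and kurtosis of a constant region are reported as
#' `NA` (degenerate-statistic sentinel).
#'
#' @param v a [volume_grid()] (preprocessed).
#' @param m a congruent [roi_mask()] with at least 2 voxels.
#' @param bin_width grey-level bin width used for Entropy/Uniformity.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(v, m, bin_width = 25) {
  x <- v$data[m$voxels]
  if (length(x) < 2L) {
    stop("degenerate ROI: first-order dispersion statistics need >= 2 voxels")
  }
  vox_vol <- prod(v$spacing)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE))
  inner <- x[x >= q[1] & x <= q[4]]

  bins <- discretize(x, bin_width)
  p <- tabulate(bins) / n
  p <- p[p > 0]

  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_

  c(Mean = mu,
    Median = median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    TotalEnergy = vox_vol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(x^2)),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2])
}
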