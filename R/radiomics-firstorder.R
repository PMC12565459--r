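#' The 18 first-order intensity statistics
#'
#' Standard first-order set over the raw ROI intensities; `Entropy` and
#' `Uniformity` use the fixed-bin-width discretization (min-anchored, default
#' width 25). Moments are population moments; kurtosis is uncorrected (a
#' normal sample gives ~3). For a constant ROI the variance-normalized moments
#' are defined as 0.
#'
#' @param values Numeric vector of ROI voxel intensities.
#' @param spacing Voxel spacing (for `TotalEnergy`), length 3.
#' @param bin_width Discretization bin width for `Entropy`/`Uniformity`.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, spacing = c(1, 1, 1), bin_width = 25) {
  if (length(values) == 0L) eg_abort("empty ROI", "empty_roi")
  x <- as.numeric(values)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p10 <- unname(quantile(x, 0.10)); p90 <- unname(quantile(x, 0.90))
  sub <- x[x >= p10 & x <= p90]
  lv <- floor((x - min(x)) / bin_width) + 1
  p <- tabulate(lv) / n
  p <- p[p > 0]
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = prod(spacing) * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = p10,
    firstorder_90Percentile = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = median(x),
    firstorder_InterquartileRange = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}
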