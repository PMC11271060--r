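# First-order (intensity histogram / distribution) features over a VOI.

#' First-order intensity features
#'
#' The 18 standard first-order features over masked voxels. `Energy`,
#' `TotalEnergy` and `RootMeanSquared` use intensities shifted by
#' `voxel_shift` (the voxel-array-shift convention, default 300), which
#' prevents values around zero from cancelling; all other features use raw
#' intensities. `Entropy` and `Uniformity` are computed from the fixed
#' bin-width histogram (see [discretize()]).
#'
#' Moment-based features of a constant region are degenerate: `Variance` is
#' 0 and `Skewness`/`Kurtosis` are defined as 0 there.
#'
#' @param volume an [image_volume()] or 3D array.
#' @param mask binary mask, non-empty.
#' @param bin_width histogram bin width (default 25).
#' @param voxel_shift additive shift for the energy-type features (default 300).
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(volume, mask, bin_width = 25,
                                 voxel_shift = 300) {
  x <- if (inherits(volume, "image_volume")) volume$values else volume
  spacing <- if (inherits(volume, "image_volume")) volume$spacing else c(1, 1, 1)
  m <- check_mask(mask, if (inherits(volume, "image_volume")) volume else NULL)
  if (!identical(dim(m), dim(x))) stop_config("mask grid does not match volume")
  v <- x[m > 0]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  qs <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inter <- v[v >= qs[1] & v <= qs[4]]
  shifted <- v + voxel_shift
  energy <- sum(shifted^2)
  disc <- discretize(x, m, bin_width = bin_width)
  p <- tabulate(disc$levels[disc$mask], nbins = disc$n_levels)
  p <- p[p > 0] / n
  c(Mean = mu,
    Median = stats::median(v),
    Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Energy = energy,
    TotalEnergy = prod(spacing) * energy,
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    Maximum = max(v),
    Range = max(v) - min(v),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    InterquartileRange = qs[3] - qs[2],
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inter - mean(inter))),
    RootMeanSquared = sqrt(energy / n),
    Uniformity = sum(p^2))
}
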