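#' Discretization settings for texture features
#'
#' Gray-level discretization applied to the masked intensities of every image
#' before texture-matrix construction. Exactly one of `bin_width` /
#' `bin_count` is active. The default is a fixed bin width of 25
#' (HU-equivalent on the original image; the same width is applied to
#' derivative-image intensities), which keeps bin edges comparable across
#' patients.
#'
#' @param bin_width positive scalar, width of each gray-level bin.
#' @param bin_count integer >= 2, number of bins (alternative mode).
#' @return list with class `discretization_config`.
#' @export
discretization_config <- function(bin_width = 25, bin_count = NULL) {
  if (is.null(bin_width) == is.null(bin_count)) {
    stop("exactly one of `bin_width` and `bin_count` must be given")
  }
  if (!is.null(bin_width) && bin_width <= 0) stop("`bin_width` must be > 0")
  if (!is.null(bin_count) && bin_count < 2) stop("`bin_count` must be >= 2")
  structure(list(bin_width = bin_width, bin_count = bin_count),
            class = "discretization_config")
}

#' Discretize intensities to gray levels
#'
#' Fixed-bin-width mode: `level = floor((v - min(v)) / W) + 1`; the maximum
#' value falls in the last occupied bin. Fixed-bin-count mode splits
#' `[min, max]` into `bin_count` equal bins with the top value clamped into
#' the last bin; a constant input maps to the single level 1.
#'
#' @param values numeric vector (non-empty).
#' @param config a [discretization_config()].
#' @return integer vector of gray levels starting at 1.
#' @export
discretize <- function(values, config = discretization_config()) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  lo <- min(values)
  if (!is.null(config$bin_width)) {
    lev <- floor((values - lo) / config$bin_width) + 1
  } else {
    rng <- max(values) - lo
    if (rng == 0) return(rep(1L, length(values)))
    w <- rng / config$bin_count
    lev <- pmin(floor((values - lo) / w) + 1, config$bin_count)
  }
  as.integer(lev)
}

plog2 <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  dim(out) <- dim(p)
  out
}

#' First-order (intensity histogram) features
#'
#' The 18 standard first-order statistics of the masked intensities. Entropy
#' and Uniformity are computed on the discretized histogram; all others on the
#' raw values. Skewness and (non-excess) Kurtosis of a zero-variance input are
#' reported as 0. Moments use the population (1/N) convention; the Kurtosis of
#' a normal sample is therefore approximately 3.
#'
#' @param values numeric vector of masked intensities (non-empty).
#' @param config a [discretization_config()].
#' @param voxel_volume voxel volume in mm^3 (for TotalEnergy).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(values, config = discretization_config(),
                                 voxel_volume = 1) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  qs <- unname(quantile(values, c(0.10, 0.25, 0.75, 0.90), type = 7))
  lev <- discretize(values, config)
  p <- tabulate(lev) / n
  inner <- values[values >= qs[1] & values <= qs[4]]
  rmad <- if (length(inner)) mean(abs(inner - mean(inner))) else 0
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else 0
  c(Energy = sum(values^2),
    Entropy = -sum(plog2(p)),
    InterquartileRange = qs[3] - qs[2],
    Kurtosis = kurt,
    Maximum = max(values),
    Mean = mu,
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    Median = median(values),
    Minimum = min(values),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    Range = max(values) - min(values),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = skew,
    TotalEnergy = voxel_volume * sum(values^2),
    Uniformity = sum(p^2),
    Variance = m2)
}
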