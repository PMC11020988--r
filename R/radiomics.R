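# The ten first-order tumor features. Conventional features are computed on
# raw voxel SUVs; kurtosis, skewness, entropy and uniformity on the SUV
# intensity histogram (fixed bin number over the VOI's [min, max]).

#' Construct a HistogramConfig
#'
#' @param nBins number of equal-width bins (default 64, the common first-order
#'   fixed-bin-number convention).
#' @param excessKurtosis subtract 3 from kurtosis (default TRUE).
#' @return a validated [HistogramConfig-class].
#' @export
histogramConfig <- function(nBins = 64L, excessKurtosis = TRUE) {
  new("HistogramConfig", nBins = as.integer(nBins),
      excessKurtosis = excessKurtosis)
}

#' @keywords internal
#' @noRd
maskedValues <- function(volume, mask) {
  if (!identical(dim(volume@values), dim(mask@values)))
    stop("mask and volume grids differ")
  vals <- volume@values[mask@values]
  if (length(vals) == 0L) stop("mask is empty")
  vals
}

#' Conventional first-order tumor features
#'
#' Maximum/mean/median SUV over the masked voxels, MTV (voxel count times
#' voxel volume, cm^3), TLG (MTV times mean SUV, grams under the unit-density
#' convention) and CoV (population SD / mean).
#'
#' @param volume an [SUVVolume-class].
#' @param mask a non-empty, grid-aligned [VOIMask-class].
#' @param sdType `"population"` (divisor n, default) or `"sample"` (n - 1)
#'   for the CoV numerator.
#' @return named numeric: `max_suv`, `mean_suv`, `median_suv`, `mtv_cm3`,
#'   `tlg_g`, `cov_suv`.
#' @examples
#' vol <- SUVVolume(array(5, c(5, 5, 4)))
#' conventionalFeatures(vol, VOIMask(array(TRUE, c(5, 5, 4))))
#' @export
conventionalFeatures <- function(volume, mask, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  vals <- maskedValues(volume, mask)
  m <- mean(vals)
  if (m == 0) stop("all-zero VOI: CoV is undefined")
  s <- stats::sd(vals)
  if (length(vals) == 1L) s <- 0
  if (sdType == "population") s <- s * sqrt((length(vals) - 1) / length(vals))
  mtv <- length(vals) * voxelVolumeMm3(volume) / 1000
  c(max_suv = max(vals), mean_suv = m, median_suv = stats::median(vals),
    mtv_cm3 = mtv, tlg_g = mtv * m, cov_suv = s / m)
}

#' SUV intensity histogram of a VOI
#'
#' Partitions `[min, max]` of the masked values into `nBins` equal-width
#' half-open bins (the last bin closed) and returns the bin probabilities. A
#' degenerate VOI (min = max) puts all mass in bin 1.
#'
#' @param volume an [SUVVolume-class].
#' @param mask a non-empty [VOIMask-class].
#' @param config a [HistogramConfig-class].
#' @return list: `p` (probabilities, sums to 1), `binCenters`, `breaks`,
#'   `degenerate` (TRUE when min = max).
#' @export
intensityHistogram <- function(volume, mask, config = histogramConfig()) {
  vals <- maskedValues(volume, mask)
  n <- config@nBins
  mn <- min(vals); mx <- max(vals)
  breaks <- seq(mn, mx, length.out = n + 1)
  if (mx == mn) {
    p <- c(1, rep(0, n - 1))
    centers <- rep(mn, n)
    return(list(p = p, binCenters = centers, breaks = breaks, degenerate = TRUE))
  }
  idx <- pmin(floor((vals - mn) / (mx - mn) * n) + 1L, n)  # last bin closed
  p <- tabulate(idx, nbins = n) / length(vals)
  centers <- (breaks[-1] + breaks[-(n + 1)]) / 2
  list(p = p, binCenters = centers, breaks = breaks, degenerate = FALSE)
}

#' Intensity-histogram features
#'
#' Entropy (bits), uniformity (sum of squared probabilities) and the skewness
#' and kurtosis of the discretized distribution (probability-weighted moments
#' of the bin-centre values). With a single occupied bin the variance is zero,
#' skewness/kurtosis are returned as 0 and flagged `degenerate`.
#'
#' @param p bin probability vector (normalized within 1e-12).
#' @param binCenters representative value of each bin (same length as `p`).
#' @param excessKurtosis subtract 3 (default TRUE).
#' @return named numeric `kurtosis`, `skewness`, `entropy_bits`, `uniformity`
#'   with attribute `degenerate`.
#' @examples
#' histogramFeatures(rep(1 / 64, 64), seq_len(64))  # entropy 6 bits
#' @export
histogramFeatures <- function(p, binCenters, excessKurtosis = TRUE) {
  if (length(p) == 0L || all(p == 0)) stop("empty probability vector")
  if (abs(sum(p) - 1) > 1e-12) stop("probabilities must sum to 1")
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  uniformity <- sum(p^2)
  mu <- sum(p * binCenters)
  m2 <- sum(p * (binCenters - mu)^2)
  degenerate <- m2 <= .Machine$double.eps * max(1, mu^2)
  if (degenerate) {
    skew <- 0; kurt <- 0
  } else {
    m3 <- sum(p * (binCenters - mu)^3)
    m4 <- sum(p * (binCenters - mu)^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - if (excessKurtosis) 3 else 0
  }
  out <- c(kurtosis = kurt, skewness = skew, entropy_bits = entropy,
           uniformity = uniformity)
  attr(out, "degenerate") <- degenerate
  out
}

#' All ten first-order tumor features
#'
#' @param volume an [SUVVolume-class].
#' @param mask tumor [VOIMask-class].
#' @param config a [HistogramConfig-class].
#' @param sdType CoV SD convention, see [conventionalFeatures()].
#' @return a [TumorFeatureSet-class].
#' @examples
#' vol <- SUVVolume(array(runif(100, 2, 8), c(5, 5, 4)))
#' featureVector(tumorFeatures(vol, VOIMask(array(TRUE, c(5, 5, 4)))))
#' @export
tumorFeatures <- function(volume, mask, config = histogramConfig(),
                          sdType = "population") {
  conv <- conventionalFeatures(volume, mask, sdType = sdType)
  h <- intensityHistogram(volume, mask, config)
  hf <- histogramFeatures(h$p, h$binCenters,
                          excessKurtosis = config@excessKurtosis)
  new("TumorFeatureSet",
      maxSUV = unname(conv["max_suv"]), meanSUV = unname(conv["mean_suv"]),
      medianSUV = unname(conv["median_suv"]), mtvCm3 = unname(conv["mtv_cm3"]),
      tlgG = unname(conv["tlg_g"]), covSUV = unname(conv["cov_suv"]),
      kurtosis = unname(hf["kurtosis"]), skewness = unname(hf["skewness"]),
      entropyBits = unname(hf["entropy_bits"]),
      uniformity = unname(hf["uniformity"]),
      nVoxels = sum(mask@values),
      degenerateHistogram = isTRUE(attr(hf, "degenerate")))
}

#' @rdname TumorFeatureSet-class
#' @export
setMethod("featureVector", "TumorFeatureSet", function(object) {
  c(max_suv = object@maxSUV, mean_suv = object@meanSUV,
    median_suv = object@medianSUV, mtv_cm3 = object@mtvCm3,
    tlg_g = object@tlgG, cov_suv = object@covSUV,
    kurtosis = object@kurtosis, skewness = object@skewness,
    entropy = object@entropyBits, uniformity = object@uniformity)
})

setMethod("show", "TumorFeatureSet", function(object) {
  fv <- featureVector(object)
  cat("TumorFeatureSet (", object@nVoxels, " voxels)\n", sep = "")
  for (nm in names(fv)) cat(sprintf("  %-10s %.6g\n", nm, fv[[nm]]))
  if (object@degenerateHistogram)
    cat("  [degenerate histogram: skewness/kurtosis set to 0]\n")
})
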