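# Adaptive-threshold tumor delineation. The threshold
#   weight * mean(SUV of tumor voxels strictly above coreFraction * max) + background
# is self-referential (the threshold defines the tumor that defines the core),
# so it is applied as a fixed-point iteration over seed-connected components.

#' Construct a SegmentationConfig
#'
#' @param coreFraction fraction of the tumor maximum defining the hot core
#'   (default 0.70; voxels strictly above it are the core).
#' @param weight multiplier on the core mean (default 0.30).
#' @param backgroundMode `"shell"` or `"explicit_mask"`.
#' @param shellInnerMM,shellOuterMM background shell distance band, mm.
#' @param maxIterations iteration cap; 1 applies the formula once.
#' @param connectivity 6, 18 or 26.
#' @return a validated [SegmentationConfig-class].
#' @export
segmentationConfig <- function(coreFraction = 0.70, weight = 0.30,
                               backgroundMode = c("shell", "explicit_mask"),
                               shellInnerMM = 8, shellOuterMM = 16,
                               maxIterations = 20L, connectivity = 26L) {
  new("SegmentationConfig", coreFraction = coreFraction, weight = weight,
      backgroundMode = match.arg(backgroundMode),
      shellInnerMM = shellInnerMM, shellOuterMM = shellOuterMM,
      maxIterations = as.integer(maxIterations),
      connectivity = as.integer(connectivity))
}

#' Adaptive SUV threshold from a tumor estimate and a background level
#'
#' Returns `weight * mean(core) + backgroundMean`, where the core is the set
#' of voxels inside `tumorEstimate` with SUV strictly greater than
#' `coreFraction` times the maximum SUV inside the estimate. The threshold is
#' affine in the background: increasing the background by delta increases the
#' threshold by exactly delta.
#'
#' @param volume an [SUVVolume-class].
#' @param tumorEstimate non-empty [VOIMask-class] over the same grid.
#' @param backgroundMean mean background SUV (>= 0).
#' @param config a [SegmentationConfig-class].
#' @return the SUV threshold (scalar).
#' @examples
#' vol <- SUVVolume(array(10, c(3, 3, 3)))
#' est <- VOIMask(array(TRUE, c(3, 3, 3)))
#' nestleThreshold(vol, est, backgroundMean = 1)  # 0.3 * 10 + 1 = 4
#' @export
nestleThreshold <- function(volume, tumorEstimate, backgroundMean,
                            config = segmentationConfig()) {
  vals <- volume@values[tumorEstimate@values]
  if (length(vals) == 0L) stop("tumor estimate is empty")
  if (backgroundMean < 0) stop("background mean must be non-negative")
  mx <- max(vals)
  core <- vals[vals > config@coreFraction * mx]
  # strict ">" only empties the core for an all-zero estimate (max > 0.7*max
  # holds whenever max > 0); fall back to the whole estimate in that case
  if (length(core) == 0L) core <- vals
  config@weight * mean(core) + backgroundMean
}

#' @keywords internal
#' @noRd
seedComponent <- function(above, dims, seedLinear, connectivity) {
  array(.cc_from_seed(as.logical(above), as.integer(dims),
                      as.integer(seedLinear - 1L), as.integer(connectivity)),
        dim = dims)
}

#' Delineate a tumor by fixed-point adaptive thresholding
#'
#' Starting from the connected component around the seed at half the local
#' maximum SUV, each iteration (1) measures the background as the mean SUV in
#' a shell `shellInnerMM`--`shellOuterMM` mm from the current estimate
#' (excluding any supplied organ masks), or in an explicit background mask;
#' (2) computes the adaptive threshold via [nestleThreshold()]; and (3)
#' re-extracts the seed-containing component of voxels strictly above the
#' threshold. Iteration stops when the mask repeats or `maxIterations` is
#' reached (then `converged` is FALSE, with a warning).
#'
#' @param volume an [SUVVolume-class].
#' @param seedPointMM world position (mm) inside the tumor.
#' @param config a [SegmentationConfig-class].
#' @param organMasks optional list of [VOIMask-class] excluded from the
#'   background shell (reference organs near the tumor).
#' @param backgroundMask explicit background [VOIMask-class], required when
#'   `backgroundMode = "explicit_mask"`.
#' @param localMaxRadiusMM search radius (mm) around the seed for the local
#'   maximum used to initialize the estimate.
#' @return a [TumorDelineation-class].
#' @export
delineateTumor <- function(volume, seedPointMM, config = segmentationConfig(),
                           organMasks = list(), backgroundMask = NULL,
                           localMaxRadiusMM = 12) {
  d <- dim(volume@values)
  seedIdx <- worldToIndex(volume, seedPointMM)
  if (volume@values[seedIdx[1], seedIdx[2], seedIdx[3]] <= 0)
    stop("SUV at the seed point must be positive")
  if (config@backgroundMode == "explicit_mask" && is.null(backgroundMask))
    stop("backgroundMode 'explicit_mask' requires a backgroundMask")

  exclude <- array(FALSE, dim = d)
  for (m in organMasks) exclude <- exclude | m@values

  # initialization: component around the seed above half the local maximum
  ball <- sphereMask(volume, seedPointMM, 2 * localMaxRadiusMM)@values
  ballVals <- volume@values[ball]
  localMax <- max(ballVals)
  hotLinear <- which(ball & volume@values == localMax)[1]
  thr <- 0.5 * localMax
  above <- volume@values > thr
  seedLinear <- seedIdx[1] + d[1] * ((seedIdx[2] - 1) + d[2] * (seedIdx[3] - 1))
  compSeed <- if (above[seedLinear]) seedLinear else hotLinear
  est <- seedComponent(above, d, compSeed, config@connectivity)
  if (!any(est)) stop("initial tumor estimate is empty at the seed")

  bg <- NA_real_
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(config@maxIterations)) {
    iterations <- it
    if (config@backgroundMode == "shell") {
      shell <- array(.shell_mask(as.logical(est), as.integer(d),
                                 as.numeric(volume@spacing),
                                 config@shellInnerMM, config@shellOuterMM),
                     dim = d)
      shell <- shell & !exclude
      if (!any(shell)) stop("background shell is empty")
      bg <- mean(volume@values[shell])
    } else {
      bgm <- backgroundMask@values & !est
      if (!any(bgm)) stop("background mask is empty (or inside the estimate)")
      bg <- mean(volume@values[bgm])
    }
    estMask <- VOIMask(est, spacing = volume@spacing, origin = volume@origin)
    thr <- nestleThreshold(volume, estMask, bg, config)
    above <- volume@values > thr
    compSeed <- if (above[seedLinear]) seedLinear else hotLinear
    nxt <- seedComponent(above, d, compSeed, config@connectivity)
    if (!any(nxt))
      stop(sprintf("tumor estimate emptied at threshold %.4g", thr))
    if (identical(nxt, est)) { converged <- TRUE; break }
    est <- nxt
  }
  if (!converged)
    warning(sprintf("delineation did not converge in %d iterations",
                    config@maxIterations))

  new("TumorDelineation",
      mask = VOIMask(est, spacing = volume@spacing, origin = volume@origin,
                     label = "tumor"),
      threshold = thr, backgroundMean = bg, iterations = iterations,
      converged = converged)
}
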