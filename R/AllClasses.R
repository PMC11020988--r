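#' @import methods
NULL

#' SUVVolume: a 3D grid of standardized-uptake values
#'
#' Holds a 3D array of SUVs (body-weight normalized, unitless) together with
#' the voxel spacing and the world position of the first voxel centre. Voxel
#' indices are 1-based in R; a voxel's world position is its centre,
#' `origin + (index - 1) * spacing` (mm).
#'
#' @slot values 3D numeric array of SUVs; finite and non-negative.
#' @slot spacing numeric(3), voxel spacing in mm per axis; strictly positive.
#' @slot origin numeric(3), world coordinates (mm) of the centre of voxel
#'   (1, 1, 1).
#' @export
setClass("SUVVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0))
)

setValidity("SUVVolume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (!all(is.finite(v))) return("values must be finite")
  if (any(v < 0)) return("SUVs must be non-negative")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive numbers (mm)")
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be three finite numbers (mm)")
  TRUE
})

#' VOIMask: a binary volume-of-interest aligned to an SUVVolume
#'
#' @slot values 3D logical array, same shape as the paired volume.
#' @slot spacing,origin grid metadata as in [SUVVolume-class].
#' @slot label free-text region label ("tumor", "liver", ...).
#' @export
setClass("VOIMask",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 label = "character"),
  prototype(spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0), label = "")
)

setValidity("VOIMask", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (!is.logical(v)) return("mask values must be logical")
  if (anyNA(v)) return("mask values must not contain NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive numbers (mm)")
  TRUE
})

#' SegmentationConfig: parameters of the adaptive-threshold delineation
#'
#' The delineation threshold is
#' `weight * mean(SUV of tumor voxels above coreFraction * max SUV) +
#'  mean background SUV`, iterated to a fixed point. Defaults follow the
#' published constants (weight 0.3, core fraction 0.70).
#'
#' @slot coreFraction fraction of the tumor maximum defining the hot core;
#'   strictly between 0 and 1 (default 0.70, the "> 70% of maximum" rule).
#' @slot weight multiplier on the core mean (default 0.30).
#' @slot backgroundMode `"shell"` (background sampled from a shell around the
#'   current estimate) or `"explicit_mask"` (caller-supplied mask).
#' @slot shellInnerMM,shellOuterMM shell distance band in mm (defaults 8, 16).
#' @slot maxIterations fixed-point iteration cap (default 20; 1 reproduces a
#'   one-shot application of the formula).
#' @slot connectivity voxel connectivity for connected components: 6, 18 or 26.
#' @export
setClass("SegmentationConfig",
  representation(coreFraction = "numeric", weight = "numeric",
                 backgroundMode = "character",
                 shellInnerMM = "numeric", shellOuterMM = "numeric",
                 maxIterations = "integer", connectivity = "integer"),
  prototype(coreFraction = 0.70, weight = 0.30, backgroundMode = "shell",
            shellInnerMM = 8, shellOuterMM = 16, maxIterations = 20L,
            connectivity = 26L)
)

setValidity("SegmentationConfig", function(object) {
  if (object@coreFraction <= 0 || object@coreFraction >= 1)
    return("coreFraction must lie strictly between 0 and 1")
  if (object@weight <= 0 || object@weight >= 1)
    return("weight must lie strictly between 0 and 1")
  if (!object@backgroundMode %in% c("shell", "explicit_mask"))
    return("backgroundMode must be 'shell' or 'explicit_mask'")
  if (object@shellInnerMM <= 0 || object@shellOuterMM <= object@shellInnerMM)
    return("need shellOuterMM > shellInnerMM > 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' TumorDelineation: result of the adaptive-threshold segmentation
#'
#' @slot mask the converged tumor [VOIMask-class].
#' @slot threshold final SUV threshold.
#' @slot backgroundMean background mean SUV used at the final iteration.
#' @slot iterations number of fixed-point iterations run.
#' @slot converged FALSE when the iteration cap was hit before stability.
#' @export
setClass("TumorDelineation",
  representation(mask = "VOIMask", threshold = "numeric",
                 backgroundMean = "numeric", iterations = "integer",
                 converged = "logical")
)

#' HistogramConfig: SUV intensity-histogram discretization
#'
#' Fixed bin number over the VOI's `[min, max]` range; bins are half-open with
#' the last bin closed, so entropy/uniformity (and skewness/kurtosis, computed
#' on bin centres) are invariant to positive affine rescaling of the SUVs.
#'
#' @slot nBins number of equal-width bins (default 64).
#' @slot excessKurtosis report kurtosis as excess (minus 3; default TRUE).
#' @export
setClass("HistogramConfig",
  representation(nBins = "integer", excessKurtosis = "logical"),
  prototype(nBins = 64L, excessKurtosis = TRUE)
)

setValidity("HistogramConfig", function(object) {
  if (object@nBins < 2L) return("nBins must be >= 2")
  TRUE
})

#' TumorFeatureSet: the ten first-order tumor features
#'
#' Six conventional features (maximum/mean/median SUV, MTV, TLG, CoV) computed
#' on raw voxel values, and four intensity-histogram features (kurtosis,
#' skewness, entropy, uniformity) computed on the discretized SUV histogram.
#'
#' @slot maxSUV,meanSUV,medianSUV SUV statistics over the masked voxels.
#' @slot mtvCm3 metabolic tumor volume, cm^3 (voxel count x voxel volume).
#' @slot tlgG total lesion glycolysis, grams (MTV x mean SUV, unit density).
#' @slot covSUV population SD / mean of masked SUVs (metabolic heterogeneity).
#' @slot kurtosis,skewness histogram shape statistics (kurtosis excess by
#'   default); both 0 with `degenerateHistogram = TRUE` when the histogram has
#'   zero variance.
#' @slot entropyBits histogram entropy, bits.
#' @slot uniformity sum of squared bin probabilities.
#' @slot nVoxels number of masked voxels.
#' @slot degenerateHistogram TRUE when skewness/kurtosis were undefined.
#' @export
setClass("TumorFeatureSet",
  representation(maxSUV = "numeric", meanSUV = "numeric", medianSUV = "numeric",
                 mtvCm3 = "numeric", tlgG = "numeric", covSUV = "numeric",
                 kurtosis = "numeric", skewness = "numeric",
                 entropyBits = "numeric", uniformity = "numeric",
                 nVoxels = "integer", degenerateHistogram = "logical")
)

setValidity("TumorFeatureSet", function(object) {
  if (object@mtvCm3 <= 0) return("mtvCm3 must be positive")
  if (abs(object@tlgG - object@mtvCm3 * object@meanSUV) >
      1e-9 * max(1, abs(object@tlgG)))
    return("TLG must equal MTV x mean SUV")
  if (object@uniformity < 0 || object@uniformity > 1)
    return("uniformity must lie in [0, 1]")
  if (object@covSUV < 0) return("covSUV must be non-negative")
  TRUE
})

#' ReferenceUptake: bone-marrow, liver and spleen uptake with BLR/SLR
#'
#' @slot bmSUV mean of the six per-vertebra core SUVs (the BM SUV).
#' @slot liverSUV,spleenSUV mean SUV of the spherical organ VOIs.
#' @slot blr bone-marrow-to-liver uptake ratio, `bmSUV / liverSUV`.
#' @slot slr spleen-to-liver uptake ratio, `spleenSUV / liverSUV`.
#' @slot perVertebraSUV the six vertebral core SUVs.
#' @slot uniformFallback logical(6); TRUE where a vertebral VOI was uniform and
#'   the strict 75%-of-maximum rule fell back to all voxels.
#' @export
setClass("ReferenceUptake",
  representation(bmSUV = "numeric", liverSUV = "numeric", spleenSUV = "numeric",
                 blr = "numeric", slr = "numeric", perVertebraSUV = "numeric",
                 uniformFallback = "logical")
)

setValidity("ReferenceUptake", function(object) {
  if (length(object@perVertebraSUV) != 6L)
    return("perVertebraSUV must contain six values")
  if (any(c(object@bmSUV, object@liverSUV, object@spleenSUV) <= 0))
    return("reference SUVs must be positive")
  if (abs(object@blr - object@bmSUV / object@liverSUV) > 1e-12 * object@blr ||
      abs(object@slr - object@spleenSUV / object@liverSUV) > 1e-12 * object@slr)
    return("blr/slr inconsistent with the stored SUVs")
  TRUE
})

#' PhantomSpec: geometry and intensity model of a synthetic PET phantom
#'
#' Describes a body-like grid holding a heterogeneous spherical tumor plus
#' liver, spleen and six vertebral reference regions, each filled with a
#' smoothed Gaussian random field over a noisy background.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot spacing numeric(3) voxel spacing in mm (default 4.07 x 4.07 x 2.5,
#'   the analysis grid).
#' @slot backgroundMean,backgroundSD background SUV level and marginal SD.
#' @slot tumorCenter,tumorRadius sphere geometry in mm (world coordinates).
#' @slot tumorMean tumor mean SUV.
#' @slot tumorTextureSD marginal SD of the tumor texture field (sets the true
#'   CoV = tumorTextureSD / tumorMean).
#' @slot textureCorrLenMM correlation length (mm) of the Gaussian smoothing of
#'   the texture field; 0 gives white noise.
#' @slot organSpecs data.frame with columns label, cx, cy, cz, radius, mean,
#'   sd; labels must include liver, spleen and vertebra_1..vertebra_6.
#' @slot noiseSD global additive Gaussian noise SD (SUV); negative values are
#'   clipped to 0 after noise is added.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 backgroundMean = "numeric", backgroundSD = "numeric",
                 tumorCenter = "numeric", tumorRadius = "numeric",
                 tumorMean = "numeric", tumorTextureSD = "numeric",
                 textureCorrLenMM = "numeric", organSpecs = "data.frame",
                 noiseSD = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    return("gridShape must be three integers >= 4")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (object@backgroundMean <= 0 || object@tumorMean <= 0)
    return("SUV means must be positive")
  if (object@tumorRadius <= 0) return("tumorRadius must be positive")
  if (object@backgroundSD < 0 || object@tumorTextureSD < 0 ||
      object@noiseSD < 0 || object@textureCorrLenMM < 0)
    return("SDs and correlation length must be non-negative")
  os <- object@organSpecs
  need <- c("label", "cx", "cy", "cz", "radius", "mean", "sd")
  if (!all(need %in% names(os)))
    return("organSpecs needs columns label, cx, cy, cz, radius, mean, sd")
  nv <- sum(grepl("^vertebra_[1-6]$", os$label))
  if (nv != 6L) return("organSpecs must contain exactly six vertebrae")
  if (any(os$radius <= 0) || any(os$mean <= 0))
    return("organ radii and SUV means must be positive")
  # pairwise non-overlap (tumor + organs), by centre distance vs radius sum
  cen <- rbind(object@tumorCenter, as.matrix(os[, c("cx", "cy", "cz")]))
  rad <- c(object@tumorRadius, os$radius)
  lab <- c("tumor", os$label)
  for (i in seq_len(nrow(cen) - 1L)) {
    for (j in seq(i + 1L, nrow(cen))) {
      if (sqrt(sum((cen[i, ] - cen[j, ])^2)) < rad[i] + rad[j])
        return(sprintf("regions '%s' and '%s' overlap", lab[i], lab[j]))
    }
  }
  TRUE
})

#' GroundTruth: known regions and parameters of a generated phantom
#'
#' @slot tumorMask true tumor [VOIMask-class].
#' @slot organMasks named list of [VOIMask-class] per labelled organ.
#' @slot trueTumorVolumeCm3 analytic sphere volume of the specified geometry.
#' @slot trueRegionMeans named SUV means used by the generator.
#' @export
setClass("GroundTruth",
  representation(tumorMask = "VOIMask", organMasks = "list",
                 trueTumorVolumeCm3 = "numeric", trueRegionMeans = "numeric")
)

#' CohortSpec: generative model of a synthetic patient cohort
#'
#' Patients carry clinical covariates, ordinal immunohistochemical grades
#' (CD4/CD8/CD163/IL-6/MMP-11 in {0,1,2}), log-normal imaging features whose
#' medians shift multiplicatively per grade step, and censored recurrence-free
#' survival drawn from an exponential proportional-hazards model.
#'
#' @slot nPatients cohort size (>= 2).
#' @slot gradeProbs 5 x 3 matrix of grade probabilities, rows cd4, cd8, cd163,
#'   il6, mmp11; each row sums to 1.
#' @slot featureGradeShifts data.frame (feature, marker, shift): multiplicative
#'   median shift of `feature` per grade step of `marker`.
#' @slot featureBaseMedians,featureLogSD named numeric: log-normal location
#'   (median) and log-scale SD per feature.
#' @slot logHazardCoefs named numeric log-hazard coefficients; supported names
#'   are `stage_iii_iv` (indicator), `cov_suv` (per 0.10 increase) and `slr`
#'   (per 1.0 increase).
#' @slot baselineHazardRate events/month for a median stage I-II patient.
#' @slot censoringWindow c(min, max) months of uniform administrative
#'   censoring (default 26.1 to 84.4).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", gradeProbs = "matrix",
                 featureGradeShifts = "data.frame",
                 featureBaseMedians = "numeric", featureLogSD = "numeric",
                 logHazardCoefs = "numeric", baselineHazardRate = "numeric",
                 censoringWindow = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  if (object@nPatients < 2L) return("nPatients must be >= 2")
  gp <- object@gradeProbs
  if (!identical(dim(gp), c(5L, 3L)))
    return("gradeProbs must be a 5 x 3 matrix")
  if (any(gp < 0) || any(abs(rowSums(gp) - 1) > 1e-8))
    return("gradeProbs rows must be probabilities summing to 1")
  cw <- object@censoringWindow
  if (length(cw) != 2L || cw[1] <= 0 || cw[2] <= cw[1])
    return("censoringWindow must be positive and ordered")
  if (length(object@logHazardCoefs) == 0L)
    return("logHazardCoefs must not be empty")
  if (!all(is.finite(object@logHazardCoefs)))
    return("logHazardCoefs must be finite")
  if (object@baselineHazardRate <= 0)
    return("baselineHazardRate must be positive")
  TRUE
})
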