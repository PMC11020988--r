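# Reference-organ uptake: per-vertebra bone-marrow SUV (mean of the core
# above 75% of the VOI maximum), liver and spleen spherical-VOI means, and
# the BLR / SLR ratios.

#' Core-mean SUV of a vertebral VOI
#'
#' Mean SUV of the voxels in the VOI with SUV strictly greater than
#' `coreFraction` times the VOI maximum (the "greater than 75% of the maximum"
#' rule). Note a uniform positive VOI keeps all its voxels (max > 0.75 max);
#' the strict inequality can only empty the core when the VOI maximum is 0,
#' in which case the value falls back to the mean over all VOI voxels and is
#' flagged.
#'
#' @param volume an [SUVVolume-class].
#' @param voi a non-empty [VOIMask-class].
#' @param coreFraction core cutoff as a fraction of the maximum (default 0.75).
#' @return the core-mean SUV, with attribute `uniformFallback`.
#' @export
vertebralSUV <- function(volume, voi, coreFraction = 0.75) {
  vals <- maskedValues(volume, voi)
  core <- vals[vals > coreFraction * max(vals)]
  fallback <- length(core) == 0L
  if (fallback) core <- vals
  structure(mean(core), uniformFallback = fallback)
}

#' Bone-marrow SUV from six vertebral VOIs
#'
#' Computes [vertebralSUV()] for each of exactly six vertebral VOIs and
#' averages them (unweighted). Exclusion of degenerate vertebrae (fractures,
#' post-operative change) is the caller's responsibility: the VOIs are inputs.
#'
#' @param volume an [SUVVolume-class].
#' @param vertebralVOIs list of six non-empty [VOIMask-class].
#' @param coreFraction see [vertebralSUV()].
#' @return list: `bm_suv`, `per_vertebra_suv` (numeric(6)),
#'   `uniform_fallback` (logical(6)).
#' @export
bmSUV <- function(volume, vertebralVOIs, coreFraction = 0.75) {
  if (length(vertebralVOIs) != 6L)
    stop("exactly six vertebral VOIs are required, got ", length(vertebralVOIs))
  per <- vapply(vertebralVOIs, function(v) {
    as.numeric(vertebralSUV(volume, v, coreFraction))
  }, numeric(1))
  fb <- vapply(vertebralVOIs, function(v) {
    isTRUE(attr(vertebralSUV(volume, v, coreFraction), "uniformFallback"))
  }, logical(1))
  list(bm_suv = mean(per), per_vertebra_suv = per, uniform_fallback = fb)
}

#' Mean SUV of a spherical organ VOI
#'
#' Mean over voxels whose centres lie within the sphere (no partial-volume
#' weighting). The liver protocol uses a 3-cm sphere in the right lobe; the
#' spleen a 2-cm sphere at its centre.
#'
#' @param volume an [SUVVolume-class].
#' @param centerMM sphere centre, world mm.
#' @param diameterMM sphere diameter, mm.
#' @return the mean SUV.
#' @export
organSUV <- function(volume, centerMM, diameterMM) {
  m <- sphereMask(volume, centerMM, diameterMM)
  if (!any(m@values)) stop("sphere contains no voxel centres")
  mean(volume@values[m@values])
}

#' Bone-marrow-to-liver and spleen-to-liver uptake ratios
#'
#' @param bmSuv,spleenSuv,liverSuv reference SUVs; `liverSuv` must be > 0.
#' @return named numeric `blr`, `slr`.
#' @examples
#' uptakeRatios(2.09, 2.06, 2.09)
#' @export
uptakeRatios <- function(bmSuv, spleenSuv, liverSuv) {
  if (liverSuv <= 0) stop("liver SUV must be positive")
  c(blr = bmSuv / liverSuv, slr = spleenSuv / liverSuv)
}

#' Full reference-organ uptake measurement
#'
#' Applies the whole reference protocol: six vertebral core measurements
#' averaged into the BM SUV, liver (3-cm sphere) and spleen (2-cm sphere)
#' means, and the BLR/SLR ratios.
#'
#' @param volume an [SUVVolume-class].
#' @param vertebralVOIs list of six vertebral [VOIMask-class] (or sphere
#'   centres via `vertebralCentersMM`).
#' @param liverCenterMM,spleenCenterMM organ sphere centres, world mm.
#' @param liverDiameterMM,spleenDiameterMM sphere diameters (defaults 30, 20).
#' @param vertebralCentersMM optional 6 x 3 matrix of vertebral sphere
#'   centres, used with `vertebralDiameterMM` when `vertebralVOIs` is NULL.
#' @param vertebralDiameterMM vertebral sphere diameter (default 15 mm).
#' @param coreFraction vertebral core cutoff (default 0.75).
#' @return a [ReferenceUptake-class].
#' @export
referenceUptake <- function(volume, vertebralVOIs = NULL,
                            liverCenterMM, spleenCenterMM,
                            liverDiameterMM = 30, spleenDiameterMM = 20,
                            vertebralCentersMM = NULL,
                            vertebralDiameterMM = 15, coreFraction = 0.75) {
  if (is.null(vertebralVOIs)) {
    if (is.null(vertebralCentersMM))
      stop("supply vertebralVOIs or vertebralCentersMM")
    vertebralCentersMM <- as.matrix(vertebralCentersMM)
    vertebralVOIs <- lapply(seq_len(nrow(vertebralCentersMM)), function(i) {
      sphereMask(volume, vertebralCentersMM[i, ], vertebralDiameterMM,
                 label = paste0("vertebra_", i))
    })
  }
  bm <- bmSUV(volume, vertebralVOIs, coreFraction)
  liver <- organSUV(volume, liverCenterMM, liverDiameterMM)
  spleen <- organSUV(volume, spleenCenterMM, spleenDiameterMM)
  r <- uptakeRatios(bm$bm_suv, spleen, liver)
  new("ReferenceUptake", bmSUV = bm$bm_suv, liverSUV = liver,
      spleenSUV = spleen, blr = unname(r["blr"]), slr = unname(r["slr"]),
      perVertebraSUV = bm$per_vertebra_suv,
      uniformFallback = bm$uniform_fallback)
}

#' @rdname TumorFeatureSet-class
#' @export
setMethod("featureVector", "ReferenceUptake", function(object) {
  c(bm_suv = object@bmSUV, liver_suv = object@liverSUV,
    spleen_suv = object@spleenSUV, blr = object@blr, slr = object@slr)
})

setMethod("show", "ReferenceUptake", function(object) {
  cat(sprintf("ReferenceUptake: BM %.3g, liver %.3g, spleen %.3g; BLR %.3g, SLR %.3g\n",
              object@bmSUV, object@liverSUV, object@spleenSUV,
              object@blr, object@slr))
  if (any(object@uniformFallback))
    cat("  [uniform-VOI fallback used for vertebra(e) ",
        paste(which(object@uniformFallback), collapse = ", "), "]\n", sep = "")
})
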