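# Synthetic PET phantoms: a heterogeneous spherical tumor plus liver, spleen
# and six vertebral reference regions on a noisy background, with full ground
# truth. Stands in for patient images so every downstream stage is testable.

#' Run code under a fixed RNG seed without disturbing the global stream
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Default reference-organ layout for the phantom
#'
#' Liver and spleen spheres large enough to hold the 3-cm / 2-cm measurement
#' VOIs, and six vertebral bodies (7.5 mm radius) stacked 16 mm apart along z.
#'
#' @return data.frame with columns label, cx, cy, cz, radius, mean, sd.
#' @export
defaultOrganSpecs <- function() {
  vz <- seq(10, 90, by = 16)
  rbind(
    data.frame(label = "liver",  cx = 140, cy = 60,  cz = 50, radius = 24,
               mean = 2.1, sd = 0.10),
    data.frame(label = "spleen", cx = 40,  cy = 60,  cz = 50, radius = 16,
               mean = 1.7, sd = 0.10),
    data.frame(label = paste0("vertebra_", 1:6), cx = 100, cy = 160, cz = vz,
               radius = 7.5, mean = 1.8, sd = 0.15)
  )
}

#' Construct a PhantomSpec
#'
#' Defaults describe a 195 x 195 x 100 mm field of view at the
#' 4.07 x 4.07 x 2.5 mm analysis spacing with an 18.75-mm-radius tumor
#' (mean SUV 8, texture SD 2, true CoV 0.25) in a background of SUV 1.
#'
#' @param gridShape voxels per axis.
#' @param spacing voxel spacing, mm.
#' @param backgroundMean,backgroundSD background SUV level and SD.
#' @param tumorCenter,tumorRadius tumor sphere, world mm.
#' @param tumorMean,tumorTextureSD tumor mean SUV and texture marginal SD.
#' @param textureCorrLenMM texture correlation length, mm.
#' @param organSpecs organ table as from [defaultOrganSpecs()].
#' @param noiseSD global additive noise SD.
#' @param seed RNG seed.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(48L, 48L, 40L),
                        spacing = c(4.07, 4.07, 2.5),
                        backgroundMean = 1.0, backgroundSD = 0.10,
                        tumorCenter = c(60, 100, 50), tumorRadius = 18.75,
                        tumorMean = 8.0, tumorTextureSD = 2.0,
                        textureCorrLenMM = 8.0,
                        organSpecs = defaultOrganSpecs(),
                        noiseSD = 0.05, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing),
      backgroundMean = backgroundMean, backgroundSD = backgroundSD,
      tumorCenter = as.numeric(tumorCenter), tumorRadius = tumorRadius,
      tumorMean = tumorMean, tumorTextureSD = tumorTextureSD,
      textureCorrLenMM = textureCorrLenMM, organSpecs = organSpecs,
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' Smoothed Gaussian random field with unit marginal variance
#'
#' White noise convolved (circularly, via FFT) with an isotropic Gaussian
#' kernel of the given correlation length, then re-standardized so the
#' marginal SD is exactly 1 over the returned voxels.
#'
#' @keywords internal
#' @noRd
gaussianField <- function(dims, spacing, corrLenMM) {
  w <- array(stats::rnorm(prod(dims)), dim = dims)
  if (corrLenMM <= 0 || any(dims < 2)) {
    return(w)
  }
  # circularly-wrapped Gaussian kernel on the grid
  ax <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) - 1
    d <- pmin(i, dims[a] - i) * spacing[a]
    exp(-d^2 / (2 * corrLenMM^2))
  })
  k <- outer(outer(ax[[1]], ax[[2]], `*`), ax[[3]], `*`)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / prod(dims)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(array(0, dim = dims))
  (f - mean(f)) / s
}

#' Fill a masked region with a textured field of given mean and marginal SD
#' @keywords internal
#' @noRd
fillRegion <- function(values, mask, meanSUV, sdSUV, spacing, corrLenMM) {
  idx <- which(mask)
  if (length(idx) == 0L) return(values)
  if (sdSUV <= 0) {
    values[idx] <- meanSUV
    return(values)
  }
  bb <- arrayInd(idx, dim(mask))
  lo <- apply(bb, 2, min); hi <- apply(bb, 2, max)
  f <- gaussianField(hi - lo + 1L, spacing, corrLenMM)
  sub <- f[cbind(bb[, 1] - lo[1] + 1L, bb[, 2] - lo[2] + 1L, bb[, 3] - lo[3] + 1L)]
  # re-standardize over the region voxels so mean/SD are exact by construction
  s <- stats::sd(sub) * sqrt((length(sub) - 1) / length(sub))
  if (!is.finite(s) || s < .Machine$double.eps) {
    values[idx] <- meanSUV
  } else {
    values[idx] <- meanSUV + (sub - mean(sub)) / s * sdSUV
  }
  values
}

#' Generate a synthetic PET phantom with ground truth
#'
#' Builds the background as white Gaussian noise, carves the tumor and organ
#' spheres (voxel-centre membership), fills each with a smoothed Gaussian
#' random field of the specified mean and marginal SD, adds global noise, and
#' clips negative SUVs to zero (SUV is non-negative by definition).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `volume` ([SUVVolume-class]) and `truth`
#'   ([GroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7L))
#' ph$volume
#' ph$truth@trueTumorVolumeCm3
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  d <- spec@gridShape
  sp <- spec@spacing
  origin <- sp / 2  # first voxel centre half a voxel from the field edge
  extent <- d * sp

  regions <- rbind(
    data.frame(label = "tumor", cx = spec@tumorCenter[1],
               cy = spec@tumorCenter[2], cz = spec@tumorCenter[3],
               radius = spec@tumorRadius, mean = spec@tumorMean,
               sd = spec@tumorTextureSD),
    spec@organSpecs
  )
  for (i in seq_len(nrow(regions))) {
    cen <- as.numeric(regions[i, c("cx", "cy", "cz")])
    r <- regions$radius[i]
    if (any(cen - r < 0) || any(cen + r > extent))
      stop(sprintf("region '%s' exceeds the grid extent", regions$label[i]))
  }

  vol0 <- SUVVolume(array(spec@backgroundMean, dim = d), spacing = sp,
                    origin = origin)
  masks <- lapply(seq_len(nrow(regions)), function(i) {
    sphereMask(vol0, as.numeric(regions[i, c("cx", "cy", "cz")]),
               2 * regions$radius[i], label = regions$label[i])
  })
  names(masks) <- regions$label

  values <- withSeed(spec@seed, {
    v <- array(stats::rnorm(prod(d), spec@backgroundMean, spec@backgroundSD),
               dim = d)
    if (spec@backgroundSD == 0) v <- array(spec@backgroundMean, dim = d)
    for (i in seq_len(nrow(regions))) {
      # spatial correlation models tumor heterogeneity; organ uptake noise is
      # kept white so subregion means converge at the 1/sqrt(n) rate
      corr <- if (regions$label[i] == "tumor") spec@textureCorrLenMM else 0
      v <- fillRegion(v, masks[[i]]@values, regions$mean[i], regions$sd[i],
                      sp, corr)
    }
    if (spec@noiseSD > 0) v <- v + stats::rnorm(prod(d), 0, spec@noiseSD)
    v
  })

  truth <- new("GroundTruth",
    tumorMask = masks[["tumor"]],
    organMasks = masks[names(masks) != "tumor"],
    trueTumorVolumeCm3 = 4 / 3 * pi * (spec@tumorRadius / 10)^3,
    trueRegionMeans = stats::setNames(regions$mean, regions$label))

  list(volume = SUVVolume(pmax(values, 0), spacing = sp, origin = origin),
       truth = truth)
}

#' Write a phantom and its ground truth to disk
#'
#' The volume and each mask go to NIfTI-1 (`.nii.gz`); a JSON index records
#' the file names, true tumor volume and true region means.
#'
#' @param phantom result of [generatePhantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the JSON index path, invisibly.
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  volPath <- file.path(dir, paste0(prefix, "_suv.nii.gz"))
  writeSUVVolume(phantom$volume, volPath)
  tr <- phantom$truth
  maskFiles <- c(tumor = paste0(prefix, "_mask_tumor.nii.gz"))
  writeVOIMask(tr@tumorMask, file.path(dir, maskFiles[["tumor"]]))
  for (lab in names(tr@organMasks)) {
    f <- paste0(prefix, "_mask_", lab, ".nii.gz")
    writeVOIMask(tr@organMasks[[lab]], file.path(dir, f))
    maskFiles[[lab]] <- f
  }
  idx <- list(volume = basename(volPath), masks = as.list(maskFiles),
              true_tumor_volume_cm3 = tr@trueTumorVolumeCm3,
              true_region_means = as.list(tr@trueRegionMeans))
  idxPath <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(idx, idxPath, auto_unbox = TRUE, digits = NA)
  invisible(idxPath)
}
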