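#' Construct an SUVVolume
#'
#' @param values 3D numeric array of SUVs.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world coordinates (mm) of the centre of voxel (1,1,1).
#' @return an [SUVVolume-class].
#' @examples
#' vol <- SUVVolume(array(1, c(4, 4, 4)), spacing = c(4.07, 4.07, 2.5))
#' voxelVolumeMm3(vol)
#' @export
SUVVolume <- function(values, spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0)) {
  new("SUVVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a VOIMask
#'
#' @param values 3D logical array.
#' @param spacing,origin grid metadata, as in [SUVVolume()].
#' @param label region label.
#' @return a [VOIMask-class].
#' @export
VOIMask <- function(values, spacing = c(4.07, 4.07, 2.5), origin = c(0, 0, 0),
                    label = "") {
  new("VOIMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), label = label)
}

#' @rdname SUVVolume-class
#' @export
setMethod("voxelValues", "SUVVolume", function(object) object@values)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelValues", "VOIMask", function(object) object@values)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelSpacing", "SUVVolume", function(object) object@spacing)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelSpacing", "VOIMask", function(object) object@spacing)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelOrigin", "SUVVolume", function(object) object@origin)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelOrigin", "VOIMask", function(object) object@origin)
#' @rdname SUVVolume-class
#' @export
setMethod("voxelVolumeMm3", "SUVVolume", function(object) prod(object@spacing))
#' @rdname SUVVolume-class
#' @export
setMethod("voxelVolumeMm3", "VOIMask", function(object) prod(object@spacing))

setMethod("show", "SUVVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("SUVVolume: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g], mean %.3g\n",
              min(object@values), max(object@values), mean(object@values)))
})

setMethod("show", "VOIMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("VOIMask '%s': %d / %d voxels (%.3g cm^3)\n",
              object@label, sum(object@values), prod(d),
              sum(object@values) * prod(object@spacing) / 1000))
})

setMethod("show", "TumorDelineation", function(object) {
  cat(sprintf(
    "TumorDelineation: threshold %.4g (background %.4g), %d voxels, %d iteration(s)%s\n",
    object@threshold, object@backgroundMean, sum(object@mask@values),
    object@iterations, if (object@converged) "" else " [NOT converged]"))
})

# grid helpers -----------------------------------------------------------

#' World coordinates of voxel centres along each axis
#' @keywords internal
#' @noRd
axisCoords <- function(object) {
  d <- dim(object@values)
  lapply(1:3, function(a) object@origin[a] + (seq_len(d[a]) - 1) * object@spacing[a])
}

#' Convert a world position (mm) to the nearest voxel index
#' @keywords internal
#' @noRd
worldToIndex <- function(object, point_mm) {
  idx <- round((point_mm - object@origin) / object@spacing) + 1
  d <- dim(object@values)
  if (any(idx < 1) || any(idx > d))
    stop("point (", paste(signif(point_mm, 4), collapse = ", "),
         ") mm lies outside the grid")
  as.integer(idx)
}

#' Spherical VOI mask by voxel-centre inclusion
#'
#' Marks every voxel whose centre lies within `diameterMM / 2` of `centerMM`.
#' Membership is by voxel-centre inclusion with no partial-volume weighting,
#' matching the voxel-counting MTV convention.
#'
#' @param volume the reference [SUVVolume-class] (grid metadata source).
#' @param centerMM sphere centre, world mm.
#' @param diameterMM sphere diameter, mm.
#' @param label mask label.
#' @return a [VOIMask-class].
#' @export
sphereMask <- function(volume, centerMM, diameterMM, label = "sphere") {
  stopifnot(diameterMM > 0)
  ax <- axisCoords(volume)
  r2 <- (diameterMM / 2)^2
  dx2 <- (ax[[1]] - centerMM[1])^2
  dy2 <- (ax[[2]] - centerMM[2])^2
  dz2 <- (ax[[3]] - centerMM[3])^2
  m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
  VOIMask(m, spacing = volume@spacing, origin = volume@origin, label = label)
}

# NIfTI I/O --------------------------------------------------------------

#' Read and write SUV volumes and masks as NIfTI-1
#'
#' Volumes are stored with a diagonal affine built from the voxel spacing and
#' origin. Masks are stored as 0/1 and re-binarized (`> 0.5`) on read.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume an [SUVVolume-class]; `mask` a [VOIMask-class].
#' @param mask a [VOIMask-class] to write.
#' @param label label for the mask read from `path`.
#' @return `readSUVVolume` an [SUVVolume-class]; `readVOIMask` a
#'   [VOIMask-class]; the writers return `path` invisibly.
#' @export
readSUVVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- abs(RNifti::pixdim(img))[1:3]
  aff <- RNifti::xform(img)
  SUVVolume(pmax(arr, 0), spacing = sp, origin = aff[1:3, 4])
}

#' @rdname readSUVVolume
#' @export
writeSUVVolume <- function(volume, path) {
  writeGridNifti(volume@values, volume@spacing, volume@origin, path)
}

#' @rdname readSUVVolume
#' @export
readVOIMask <- function(path, label = "") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img)) > 0.5
  sp <- abs(RNifti::pixdim(img))[1:3]
  aff <- RNifti::xform(img)
  VOIMask(arr, spacing = sp, origin = aff[1:3, 4], label = label)
}

#' @rdname readSUVVolume
#' @export
writeVOIMask <- function(mask, path) {
  writeGridNifti(array(as.numeric(mask@values), dim = dim(mask@values)),
                 mask@spacing, mask@origin, path)
}

#' @keywords internal
#' @noRd
writeGridNifti <- function(arr, spacing, origin, path) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# resampling -------------------------------------------------------------

#' Resample a volume to the analysis grid
#'
#' Trilinear interpolation onto a grid with the requested spacing covering the
#' same physical extent (voxel-edge to voxel-edge) as the input; border samples
#' are clamped to the nearest voxel centre. The default target is the
#' 4.07 x 4.07 x 2.5 mm analysis grid.
#'
#' @param volume an [SUVVolume-class].
#' @param targetSpacingMM numeric(3) target spacing, mm.
#' @return a resampled [SUVVolume-class].
#' @examples
#' vol <- SUVVolume(array(runif(8 * 8 * 8, 1, 2), c(8, 8, 8)), spacing = c(5, 5, 5))
#' dim(voxelValues(resampleVolume(vol, c(4.07, 4.07, 2.5))))
#' @export
resampleVolume <- function(volume, targetSpacingMM = c(4.07, 4.07, 2.5)) {
  stopifnot(length(targetSpacingMM) == 3L, all(targetSpacingMM > 0))
  if (!all(is.finite(volume@values))) stop("input volume contains non-finite values")
  d <- dim(volume@values)
  sp <- volume@spacing
  tsp <- as.numeric(targetSpacingMM)
  extent <- d * sp
  nd <- pmax(1L, as.integer(ceiling(extent / tsp - 1e-9)))
  edge <- volume@origin - sp / 2
  norigin <- edge + tsp / 2

  # fractional (1-based) source indices of each target voxel centre, per axis
  fi <- lapply(1:3, function(a) {
    x <- norigin[a] + (seq_len(nd[a]) - 1) * tsp[a]
    f <- (x - volume@origin[a]) / sp[a] + 1
    pmin(pmax(f, 1), d[a])
  })
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(fi[[a]]), 1), max(d[a] - 1, 1)))
  w <- lapply(1:3, function(a) fi[[a]] - i0[[a]])
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, d[a]))

  G <- expand.grid(x = seq_len(nd[1]), y = seq_len(nd[2]), z = seq_len(nd[3]))
  v <- volume@values
  ix0 <- i0[[1]][G$x]; ix1 <- i1[[1]][G$x]; wx <- w[[1]][G$x]
  iy0 <- i0[[2]][G$y]; iy1 <- i1[[2]][G$y]; wy <- w[[2]][G$y]
  iz0 <- i0[[3]][G$z]; iz1 <- i1[[3]][G$z]; wz <- w[[3]][G$z]
  out <-
    v[cbind(ix0, iy0, iz0)] * (1 - wx) * (1 - wy) * (1 - wz) +
    v[cbind(ix1, iy0, iz0)] * wx       * (1 - wy) * (1 - wz) +
    v[cbind(ix0, iy1, iz0)] * (1 - wx) * wy       * (1 - wz) +
    v[cbind(ix1, iy1, iz0)] * wx       * wy       * (1 - wz) +
    v[cbind(ix0, iy0, iz1)] * (1 - wx) * (1 - wy) * wz +
    v[cbind(ix1, iy0, iz1)] * wx       * (1 - wy) * wz +
    v[cbind(ix0, iy1, iz1)] * (1 - wx) * wy       * wz +
    v[cbind(ix1, iy1, iz1)] * wx       * wy       * wz
  SUVVolume(array(pmax(out, 0), dim = nd), spacing = tsp, origin = norigin)
}
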