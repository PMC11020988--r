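#' @rdname SUVVolume-class
#' @param object an object with voxel data.
#' @export
setGeneric("voxelValues", function(object) standardGeneric("voxelValues"))

#' @rdname SUVVolume-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname SUVVolume-class
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))

#' @rdname SUVVolume-class
#' @export
setGeneric("voxelVolumeMm3", function(object) standardGeneric("voxelVolumeMm3"))

#' @rdname TumorFeatureSet-class
#' @param object a [TumorFeatureSet-class] or [ReferenceUptake-class].
#' @export
setGeneric("featureVector", function(object) standardGeneric("featureVector"))
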