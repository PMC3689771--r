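#' Accessors for image-like objects
#'
#' `voxelData()` returns the raw array, `voxelSpacing()` the per-axis mm
#' spacing, `voxelAffine()` the grid-to-world affine, `gridDim()` the grid
#' extents; `mapValues()` and `mapParams()` access a [SymmetryMap-class].
#'
#' @param x a [VoxelVolume-class] or [SymmetryMap-class].
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("mapParams", function(x) standardGeneric("mapParams"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "VoxelVolume", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("gridDim", "VoxelVolume", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("mapValues", "SymmetryMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("mapParams", "SymmetryMap", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "SymmetryMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridDim", "SymmetryMap", function(x) dim(x@values))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %s voxels, spacing (%s) mm, range [%.4g, %.4g]\n",
              paste(d, collapse = " x "),
              paste(format(object@spacing), collapse = ", "),
              min(object@data), max(object@data)))
  invisible(object)
})

setMethod("show", "SymmetryMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SymmetryMap: %s, radii {%s} mm, polarity %s, max %.4g\n",
              paste(d, collapse = " x "),
              paste(format(object@params@radiiMM), collapse = ", "),
              object@params@polarity, max(object@values)))
  invisible(object)
})

setMethod("show", "RSTParams", function(object) {
  cat(sprintf(
    "RSTParams: radii {%s} mm, alpha %g, sigma %g*n, grad cutoff %g, %s\n",
    paste(format(object@radiiMM), collapse = ", "), object@alpha,
    object@smoothSigmaFactor, object@gradThresholdFrac, object@polarity))
  invisible(object)
})

setMethod("show", "PhantomOutput", function(object) {
  cat(sprintf(
    "PhantomOutput: %s grid, %d sphere(s), %d tube(s), %d plane(s)\n",
    paste(dim(object@volume@data), collapse = " x "),
    nrow(object@truth), length(object@spec@tubes), length(object@spec@planes)))
  invisible(object)
})

#' @rdname phantomAccessors
#' @export
setGeneric("phantomVolume", function(x) standardGeneric("phantomVolume"))
#' @rdname phantomAccessors
#' @export
setGeneric("phantomMask", function(x) standardGeneric("phantomMask"))
#' @rdname phantomAccessors
#' @export
setGeneric("phantomTruth", function(x) standardGeneric("phantomTruth"))

#' Accessors for generated phantoms
#'
#' @param x a [PhantomOutput-class].
#' @return The volume, mask or ground-truth table of the phantom.
#' @name phantomAccessors
NULL

#' @rdname phantomAccessors
#' @export
setMethod("phantomVolume", "PhantomOutput", function(x) x@volume)
#' @rdname phantomAccessors
#' @export
setMethod("phantomMask", "PhantomOutput", function(x) x@mask)
#' @rdname phantomAccessors
#' @export
setMethod("phantomTruth", "PhantomOutput", function(x) x@truth)
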