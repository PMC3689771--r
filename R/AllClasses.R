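#' @import methods
NULL

#' VoxelVolume: a scalar image grid with physical spacing
#'
#' The carrier object for images, masks and symmetry maps: a 2D or 3D scalar
#' array together with per-axis voxel spacing in millimetres and a
#' grid-index-to-world-mm affine. Voxel indices are 0-based throughout the
#' package; world coordinates are millimetres in the affine's frame (for
#' NIfTI input, the header sform/qform frame).
#'
#' @slot data numeric array with 2 or 3 dimensions, each extent >= 1.
#' @slot spacing numeric vector, one strictly positive entry per axis (mm).
#' @slot affine square matrix of side \code{ndim + 1} mapping homogeneous
#'   0-based voxel indices to world mm; its linear part's column norms must
#'   equal \code{spacing}.
#'
#' @seealso [VoxelVolume()], [voxelData()], [voxelToWorld()]
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix"))

setValidity("VoxelVolume", function(object) {
  d <- dim(object@data)
  nd <- length(d)
  if (!nd %in% c(2L, 3L))
    return("data must have 2 or 3 dimensions")
  if (any(d < 1L))
    return("every grid extent must be >= 1")
  if (length(object@spacing) != nd)
    return("spacing must have one entry per data dimension")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("all spacing components must be strictly positive")
  a <- object@affine
  if (!all(dim(a) == nd + 1L))
    return(sprintf("affine must be %d x %d", nd + 1L, nd + 1L))
  dt <- det(a)
  if (!is.finite(dt) || abs(dt) < 1e-12)
    return("affine must be invertible")
  cn <- sqrt(colSums(a[seq_len(nd), seq_len(nd), drop = FALSE]^2))
  if (any(abs(cn - object@spacing) > 1e-6 * object@spacing))
    return("affine column norms must equal spacing (1e-6 relative)")
  TRUE
})

#' Construct a VoxelVolume
#'
#' @param data numeric array (2D or 3D).
#' @param spacing per-axis voxel size in mm.
#' @param affine optional grid-to-world affine; defaults to
#'   \code{diag(c(spacing, 1))}, i.e. world = index * spacing.
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(array(0, c(8, 8, 4)), spacing = c(1, 1, 3))
#' voxelSpacing(v)
#' @export
VoxelVolume <- function(data, spacing, affine = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (is.null(affine))
    affine <- diag(c(spacing, 1))
  new("VoxelVolume", data = data, spacing = spacing,
      affine = unname(as.matrix(affine)))
}

#' RST parameter set
#'
#' All knobs of the radial symmetry transform. Radii are physical (mm), so
#' the transform behaves identically on isotropic and anisotropic grids.
#'
#' @slot radiiMM strictly increasing positive radii in mm.
#' @slot alpha radial-strictness exponent (>= 1); larger values punish
#'   incomplete gradient convergence (elongated structures) harder.
#' @slot smoothSigmaFactor per-radius Gaussian scale as a fraction of the
#'   radius: sigma = smoothSigmaFactor * n mm.
#' @slot gradThresholdFrac fraction of the maximum gradient magnitude below
#'   which voxels do not vote.
#' @slot polarity "dark" (hypointense blobs), "bright", or "both".
#' @export
setClass("RSTParams",
  representation(radiiMM = "numeric", alpha = "numeric",
                 smoothSigmaFactor = "numeric", gradThresholdFrac = "numeric",
                 polarity = "character"))

setValidity("RSTParams", function(object) {
  r <- object@radiiMM
  if (length(r) < 1L || any(!is.finite(r)) || any(r <= 0))
    return("radiiMM must be nonempty and strictly positive")
  if (length(r) > 1L && any(diff(r) <= 0))
    return("radiiMM must be strictly increasing")
  if (length(object@alpha) != 1L || object@alpha < 1)
    return("alpha must be a scalar >= 1")
  if (length(object@smoothSigmaFactor) != 1L || object@smoothSigmaFactor < 0)
    return("smoothSigmaFactor must be a scalar >= 0")
  g <- object@gradThresholdFrac
  if (length(g) != 1L || g < 0 || g >= 1)
    return("gradThresholdFrac must lie in [0, 1)")
  if (!object@polarity %in% c("dark", "bright", "both"))
    return("polarity must be one of dark, bright, both")
  TRUE
})

#' Construct an RSTParams object
#'
#' Defaults target microbleeds of 2-10 mm diameter on [0, 255]-normalized
#' input: radii 1-4 mm, strictness 2, sigma = radius / 2, 5% gradient cutoff,
#' dark polarity.
#'
#' @param radiiMM physical voting radii in mm.
#' @param alpha radial-strictness exponent.
#' @param smoothSigmaFactor Gaussian scale per radius, as fraction of radius.
#' @param gradThresholdFrac relative gradient-magnitude cutoff in [0, 1).
#' @param polarity "dark", "bright" or "both".
#' @return An [RSTParams-class] object.
#' @export
RSTParams <- function(radiiMM = c(1, 2, 3, 4), alpha = 2,
                      smoothSigmaFactor = 0.5, gradThresholdFrac = 0.05,
                      polarity = "dark") {
  new("RSTParams", radiiMM = as.numeric(radiiMM), alpha = as.numeric(alpha),
      smoothSigmaFactor = as.numeric(smoothSigmaFactor),
      gradThresholdFrac = as.numeric(gradThresholdFrac),
      polarity = match.arg(polarity, c("dark", "bright", "both")))
}

#' Radial symmetry map
#'
#' Per-voxel radial symmetry values on the same grid as the input volume.
#'
#' @slot values scalar array (same extents as the transformed volume).
#' @slot spacing per-axis spacing in mm, inherited from the input.
#' @slot params the [RSTParams-class] used.
#' @export
setClass("SymmetryMap",
  representation(values = "array", spacing = "numeric", params = "RSTParams"))

setValidity("SymmetryMap", function(object) {
  if (!length(dim(object@values)) %in% c(2L, 3L))
    return("values must be a 2D or 3D array")
  if (length(object@spacing) != length(dim(object@values)))
    return("spacing must match values dimensionality")
  if (any(!is.finite(object@values)))
    return("all symmetry values must be finite")
  TRUE
})

#' Intensity normalization settings
#'
#' Percentile-based range normalization of the in-mask histogram to
#' \code{[outMin, outMax]}. The defaults (6th and 95th percentile to
#' [0, 255]) put microbleed intensities at the dark end of the output range.
#'
#' @slot pLow,pHigh percentiles in [0, 100] with pLow < pHigh.
#' @slot outMin,outMax output range bounds.
#' @slot clip clamp output into the range (TRUE) or extrapolate linearly.
#' @export
setClass("NormalizationSpec",
  representation(pLow = "numeric", pHigh = "numeric", outMin = "numeric",
                 outMax = "numeric", clip = "logical"))

setValidity("NormalizationSpec", function(object) {
  if (!(object@pLow >= 0 && object@pLow < object@pHigh && object@pHigh <= 100))
    return("require 0 <= pLow < pHigh <= 100")
  if (object@outMin >= object@outMax)
    return("require outMin < outMax")
  TRUE
})

#' Construct a NormalizationSpec
#' @param pLow,pHigh input percentiles (defaults 6 and 95).
#' @param outMin,outMax output range (defaults 0 and 255).
#' @param clip clamp to the output range (default TRUE).
#' @return A [NormalizationSpec-class] object.
#' @export
NormalizationSpec <- function(pLow = 6, pHigh = 95, outMin = 0, outMax = 255,
                              clip = TRUE) {
  new("NormalizationSpec", pLow = as.numeric(pLow), pHigh = as.numeric(pHigh),
      outMin = as.numeric(outMin), outMax = as.numeric(outMax),
      clip = isTRUE(clip))
}

#' Candidate detection thresholds
#'
#' @slot t3d threshold on the 3D radial symmetry value (> 0).
#' @slot t2d threshold on the 2D (minIP-stage) symmetry value; 0 disables
#'   the 2D stage entirely.
#' @slot connectivity 6, 18 or 26 for suprathreshold-component clustering.
#' @export
setClass("DetectionParams",
  representation(t3d = "numeric", t2d = "numeric", connectivity = "integer"))

setValidity("DetectionParams", function(object) {
  if (length(object@t3d) != 1L || !is.finite(object@t3d) || object@t3d <= 0)
    return("t3d must be a positive scalar")
  if (length(object@t2d) != 1L || !is.finite(object@t2d) || object@t2d < 0)
    return("t2d must be a scalar >= 0")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' Construct DetectionParams
#' @param t3d stage-1 threshold on the 3D symmetry value.
#' @param t2d stage-2 threshold on the 2D symmetry value (0 = stage 2 off).
#' @param connectivity component connectivity (6, 18 or 26).
#' @return A [DetectionParams-class] object.
#' @export
DetectionParams <- function(t3d, t2d = 0, connectivity = 26) {
  new("DetectionParams", t3d = as.numeric(t3d), t2d = as.numeric(t2d),
      connectivity = as.integer(connectivity))
}

#' Minimum-intensity-projection settings
#'
#' @slot slabThicknessMM physical slab height for the transversal minIP
#'   (default 12 mm: slices within +/- 6 mm of the candidate).
#' @slot roiHalfwidthMM in-plane half-width of the square region of interest.
#' @slot haloVoxels neighborhood half-width (voxels) when reading the
#'   candidate's 2D score off the patch map.
#' @export
setClass("MinIPSpec",
  representation(slabThicknessMM = "numeric", roiHalfwidthMM = "numeric",
                 haloVoxels = "integer"))

setValidity("MinIPSpec", function(object) {
  if (object@slabThicknessMM <= 0) return("slabThicknessMM must be > 0")
  if (object@roiHalfwidthMM <= 0) return("roiHalfwidthMM must be > 0")
  if (object@haloVoxels < 0L) return("haloVoxels must be >= 0")
  TRUE
})

#' Construct a MinIPSpec
#' @param slabThicknessMM slab height in mm (default 12).
#' @param roiHalfwidthMM square ROI half-width in mm (default 12); must be at
#'   least the largest RST radius.
#' @param haloVoxels half-width of the score-reading neighborhood (default 1).
#' @return A [MinIPSpec-class] object.
#' @export
MinIPSpec <- function(slabThicknessMM = 12, roiHalfwidthMM = 12,
                      haloVoxels = 1) {
  new("MinIPSpec", slabThicknessMM = as.numeric(slabThicknessMM),
      roiHalfwidthMM = as.numeric(roiHalfwidthMM),
      haloVoxels = as.integer(haloVoxels))
}

#' Synthetic phantom specification
#'
#' Describes one phantom: grid geometry, textured noisy background, and dark
#' lesions — spheres (microbleed analogues), curvilinear tubes (vessel
#' analogues) and planes (fissure analogues). Lesion coordinates are world mm
#' under the phantom's diagonal affine (world = index * spacing).
#'
#' @slot extents grid size (nx, ny, nz).
#' @slot spacingMM voxel size in mm; default (1, 1, 3) mimics thick-slice
#'   T2*-weighted acquisitions.
#' @slot backgroundMean,noiseSigma background intensity and additive Gaussian
#'   noise sd.
#' @slot textureSigma,textureScaleMM sd and correlation length of the smooth
#'   low-frequency background texture that emulates tissue contrast; the
#'   texture dominates the intensity histogram the way gray/white matter
#'   contrast does on real scans, so percentile normalization sees a
#'   realistic dynamic range.
#' @slot spheres data.frame(x, y, z, diameter, depth): center mm, diameter mm
#'   in [2, 10], fractional intensity drop in (0, 1].
#' @slot tubes list of list(points = n x 3 mm matrix, radius, depth).
#' @slot planes list of list(origin, normal, thickness, depth).
#' @slot maskMarginMM erosion of the all-inside mask from the grid faces.
#' @slot seed RNG seed for the noise field.
#' @export
setClass("PhantomSpec",
  representation(extents = "integer", spacingMM = "numeric",
                 backgroundMean = "numeric", noiseSigma = "numeric",
                 textureSigma = "numeric", textureScaleMM = "numeric",
                 spheres = "data.frame", tubes = "list", planes = "list",
                 maskMarginMM = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@extents) != 3L || any(object@extents < 1L))
    return("extents must be three positive integers")
  if (length(object@spacingMM) != 3L || any(object@spacingMM <= 0))
    return("spacingMM must be three positive values")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@textureSigma < 0) return("textureSigma must be >= 0")
  if (object@textureScaleMM <= 0) return("textureScaleMM must be > 0")
  s <- object@spheres
  if (nrow(s) > 0) {
    if (!all(c("x", "y", "z", "diameter", "depth") %in% names(s)))
      return("spheres needs columns x, y, z, diameter, depth")
    if (any(s$diameter <= 0)) return("sphere diameters must be positive")
    if (any(s$depth <= 0 | s$depth > 1)) return("sphere depths must be in (0, 1]")
  }
  for (tb in object@tubes) {
    if (tb$radius <= 0) return("tube radii must be positive")
    if (tb$depth <= 0 || tb$depth > 1) return("tube depths must be in (0, 1]")
  }
  for (pl in object@planes) {
    if (pl$thickness <= 0) return("plane thickness must be positive")
    if (pl$depth <= 0 || pl$depth > 1) return("plane depths must be in (0, 1]")
  }
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param extents grid size triple (default 96 x 96 x 40).
#' @param spacingMM voxel size in mm (default c(1, 1, 3)).
#' @param backgroundMean background intensity (default 200).
#' @param noiseSigma additive Gaussian noise sd (default 8).
#' @param textureSigma sd of the smooth background texture (default 30).
#' @param textureScaleMM texture correlation length in mm (default 20).
#' @param spheres data.frame(x, y, z, diameter, depth) or NULL.
#' @param tubes list of list(points, radius, depth) polyline tubes.
#' @param planes list of list(origin, normal, thickness, depth).
#' @param maskMarginMM face erosion of the mask in mm (default 3).
#' @param seed noise RNG seed.
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(extents = c(96, 96, 40), spacingMM = c(1, 1, 3),
                        backgroundMean = 200, noiseSigma = 8,
                        textureSigma = 30, textureScaleMM = 20,
                        spheres = NULL, tubes = list(), planes = list(),
                        maskMarginMM = 3, seed = 1) {
  if (is.null(spheres))
    spheres <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          diameter = numeric(0), depth = numeric(0))
  new("PhantomSpec", extents = as.integer(extents),
      spacingMM = as.numeric(spacingMM),
      backgroundMean = as.numeric(backgroundMean),
      noiseSigma = as.numeric(noiseSigma),
      textureSigma = as.numeric(textureSigma),
      textureScaleMM = as.numeric(textureScaleMM), spheres = spheres,
      tubes = tubes, planes = planes, maskMarginMM = as.numeric(maskMarginMM),
      seed = as.integer(seed))
}

#' Generated phantom with ground truth
#'
#' @slot volume the synthetic intensity [VoxelVolume-class].
#' @slot mask binary inclusion mask on the same grid (nonzero = inside).
#' @slot truth data.frame(id, x_mm, y_mm, z_mm, label) with one row per
#'   sphere; label is "definite" for diameter >= 3 mm else "possible".
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomOutput",
  representation(volume = "VoxelVolume", mask = "VoxelVolume",
                 truth = "data.frame", spec = "PhantomSpec"))

setValidity("PhantomOutput", function(object) {
  if (nrow(object@truth) != nrow(object@spec@spheres))
    return("truth must have one entry per sphere")
  if (!any(object@mask@data != 0)) return("mask must be nonempty")
  TRUE
})
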