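#' @import methods
NULL

# One coordinate convention throughout: arrays are column-major with
# dim = (nx, ny, nz); the physical coordinate of voxel (ix, iy, iz)
# (1-based in R) is origin + ((ix-1)*vx, (iy-1)*vy, (iz-1)*vz), so voxel
# centres sit on integer multiples of the voxel pitch. A micrometre
# coordinate belongs to the voxel whose centre is nearest, with the upper
# boundary half-open (x exactly midway between two centres goes up).

#' Anisotropic 3D grayscale image stack
#'
#' The universal image carrier of the package: a 3D array of non-negative
#' intensities with physical voxel sizes in micrometres. The array is
#' indexed `[ix, iy, iz]` and the physical coordinate of a voxel centre is
#' `origin + (index - 1) * voxelSize` per axis.
#'
#' @slot voxels 3D numeric or integer array of intensities (>= 0).
#' @slot voxelSize numeric(3), voxel pitch in micrometres (x, y, z).
#' @slot origin numeric(3), physical coordinate of voxel (1,1,1) in
#'   micrometres.
#'
#' @export
setClass("ImageStack3D",
  representation(voxels = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("ImageStack3D", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be three positive finite values (um)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (um)")
  mn <- suppressWarnings(min(object@voxels))
  if (is.finite(mn) && mn < 0)
    return("intensities must be non-negative")
  TRUE
})

#' Construct an ImageStack3D
#'
#' @param voxels 3D array of non-negative intensities, dim `(nx, ny, nz)`.
#' @param voxelSize numeric(3), voxel pitch in micrometres (x, y, z).
#' @param origin numeric(3), physical coordinate of voxel (1,1,1).
#' @return An [ImageStack3D-class] object.
#' @examples
#' st <- ImageStack3D(array(0L, dim = c(4, 4, 2)), c(1, 1, 2))
#' dim(st)
#' @export
ImageStack3D <- function(voxels, voxelSize, origin = c(0, 0, 0)) {
  new("ImageStack3D", voxels = voxels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Binary foreground mask aligned with a parent stack
#'
#' @slot voxels 3D logical array.
#' @slot voxelSize numeric(3), micrometres.
#' @slot origin numeric(3), micrometres.
#' @export
setClass("BinaryMask3D",
  representation(voxels = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("BinaryMask3D", function(object) {
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    return("voxels must be a 3D logical array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive values (um)")
  TRUE
})

#' Construct a BinaryMask3D
#' @param voxels 3D logical array.
#' @param voxelSize numeric(3), micrometres.
#' @param origin numeric(3), micrometres.
#' @return A [BinaryMask3D-class] object.
#' @export
BinaryMask3D <- function(voxels, voxelSize, origin = c(0, 0, 0)) {
  new("BinaryMask3D", voxels = voxels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Integer-labelled region volume
#'
#' A 3D integer array assigning every voxel to a named region; label 0 is
#' reserved for "outside". Region volumes are derived from voxel counts and
#' the voxel pitch.
#'
#' @slot labels 3D integer array of region labels (>= 0).
#' @slot voxelSize numeric(3), micrometres.
#' @slot origin numeric(3), micrometres.
#' @slot nameTable named character vector mapping label (as name) to region
#'   name.
#' @export
setClass("RegionLabelVolume",
  representation(labels = "array", voxelSize = "numeric", origin = "numeric",
                 nameTable = "character"))

setValidity("RegionLabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (min(object@labels) < 0)
    return("labels must be >= 0 (0 = outside)")
  labs <- setdiff(sort(unique(as.vector(object@labels))), 0L)
  if (!all(as.character(labs) %in% names(object@nameTable)))
    return("every nonzero label must appear in nameTable")
  TRUE
})

#' Construct a RegionLabelVolume
#' @param labels 3D integer array (0 = outside).
#' @param voxelSize numeric(3), micrometres.
#' @param nameTable named character vector, names are label numbers.
#' @param origin numeric(3), micrometres.
#' @return A [RegionLabelVolume-class] object.
#' @export
RegionLabelVolume <- function(labels, voxelSize, nameTable,
                              origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("RegionLabelVolume", labels = labels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), nameTable = nameTable)
}

#' Parameter set for the synthetic phantom generator
#'
#' Describes one synthetic labelled-soma volume: extents, voxel pitch, how
#' many somas (a count or a density), their size distribution, spacing
#' rules, axially aligned pairs, neurite clutter and the intensity/noise
#' model. See [generatePhantom()].
#'
#' @slot shapeUm numeric(3), physical extents in micrometres (x, y, z).
#' @slot voxelSizeUm numeric(3), voxel pitch in micrometres.
#' @slot nSomas integer soma count, or NA to use `density`.
#' @slot density somas per cubic millimetre (used when `nSomas` is NA).
#' @slot radiusMeanUm numeric(3), mean ellipsoid semi-axes a >= b >= c (um).
#' @slot radiusJitter fractional uniform jitter applied per semi-axis.
#' @slot minSeparationUm centre-to-centre exclusion distance (um).
#' @slot axialPairFraction fraction of somas placed as disjoint z-aligned
#'   pairs.
#' @slot neuriteDensity neurite tubes per cubic millimetre.
#' @slot somaIntensity,backgroundIntensity,noiseSigma grayscale levels.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shapeUm = "numeric", voxelSizeUm = "numeric",
                 nSomas = "integer", density = "numeric",
                 radiusMeanUm = "numeric", radiusJitter = "numeric",
                 minSeparationUm = "numeric", axialPairFraction = "numeric",
                 neuriteDensity = "numeric", somaIntensity = "numeric",
                 backgroundIntensity = "numeric", noiseSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shapeUm) != 3L || any(object@shapeUm <= 0))
    return("shapeUm must be three positive extents (um)")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    return("voxelSizeUm must be three positive values (um)")
  if (is.na(object@nSomas) && is.na(object@density))
    return("one of nSomas or density must be given")
  if (!is.na(object@nSomas) && object@nSomas < 0)
    return("nSomas must be >= 0")
  if (object@axialPairFraction < 0 || object@axialPairFraction > 1)
    return("axialPairFraction must be in [0, 1]")
  if (object@minSeparationUm < 0)
    return("minSeparationUm must be >= 0")
  if (length(object@radiusMeanUm) != 3L || any(object@radiusMeanUm <= 0))
    return("radiusMeanUm must be three positive semi-axes (um)")
  if (any(diff(object@radiusMeanUm) > 0))
    return("radiusMeanUm must be ordered a >= b >= c")
  if (object@somaIntensity <= object@backgroundIntensity)
    return("somaIntensity must exceed backgroundIntensity")
  if (object@noiseSigma < 0)
    return("noiseSigma must be >= 0")
  if (is.na(object@seed))
    return("seed must be a finite integer")
  TRUE
})

#' Ground-truth soma set emitted by the phantom generator
#'
#' The evaluation reference: one row per rasterized soma with its centre,
#' semi-axes and in-plane orientation, plus the [PhantomSpec-class] that
#' produced it. Axial pair members carry a shared `pair` id.
#'
#' @slot somas data.frame with columns `id`, `x_um`, `y_um`, `z_um`, `a_um`,
#'   `b_um`, `c_um`, `theta`, `pair`.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("GroundTruthSet",
  representation(somas = "data.frame", spec = "PhantomSpec"))

setValidity("GroundTruthSet", function(object) {
  s <- object@somas
  need <- c("id", "x_um", "y_um", "z_um", "a_um", "b_um", "c_um")
  if (!all(need %in% names(s)))
    return(paste("somas must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(s$id))
    return("soma ids must be unique")
  TRUE
})

#' Block decomposition of a large volume
#'
#' Half-open core tiles that partition the voxel grid exactly once, each
#' extended by a halo margin (clipped at the volume bounds) so that a soma
#' straddling a seam is wholly visible to the block that owns its centre.
#'
#' @slot blockSizeUm numeric(3), nominal core size in micrometres.
#' @slot haloUm scalar halo margin in micrometres.
#' @slot blocks data.frame of 0-based half-open voxel ranges: core
#'   `ix0..iz1` and padded `px0..pz1`.
#' @slot dims integer(3), voxel grid of the parent stack.
#' @slot voxelSize,origin geometry of the parent stack.
#' @export
setClass("BlockLayout",
  representation(blockSizeUm = "numeric", haloUm = "numeric",
                 blocks = "data.frame", dims = "integer",
                 voxelSize = "numeric", origin = "numeric"))

#' Sparse voxel mask of one segmented soma
#'
#' Stores the sorted 1-based linear indices of the voxels belonging to one
#' soma, together with the geometry of the parent stack.
#'
#' @slot indices sorted integer vector of 1-based linear voxel indices.
#' @slot dims integer(3) of the parent array.
#' @slot voxelSize,origin geometry of the parent stack.
#' @export
setClass("SomaMask",
  representation(indices = "integer", dims = "integer",
                 voxelSize = "numeric", origin = "numeric"))

# ---- accessors -------------------------------------------------------------

#' @describeIn ImageStack3D array of intensities
#' @param object,x an object of the documented class
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname ImageStack3D-class
#' @export
setMethod("voxels", "ImageStack3D", function(object) object@voxels)

#' @rdname BinaryMask3D-class
#' @export
setMethod("voxels", "BinaryMask3D", function(object) object@voxels)

#' Voxel pitch in micrometres
#' @param object an image-like object
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ImageStack3D", function(object) object@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BinaryMask3D", function(object) object@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "RegionLabelVolume", function(object) object@voxelSize)

#' Physical origin in micrometres
#' @param object an image-like object
#' @export
setGeneric("stackOrigin", function(object) standardGeneric("stackOrigin"))

#' @rdname stackOrigin
#' @export
setMethod("stackOrigin", "ImageStack3D", function(object) object@origin)

#' @rdname stackOrigin
#' @export
setMethod("stackOrigin", "BinaryMask3D", function(object) object@origin)

#' @rdname ImageStack3D-class
#' @export
setMethod("dim", "ImageStack3D", function(x) dim(x@voxels))

#' @rdname BinaryMask3D-class
#' @export
setMethod("dim", "BinaryMask3D", function(x) dim(x@voxels))

#' Ground-truth soma table
#' @param object a [GroundTruthSet-class]
#' @return data.frame of true somas.
#' @export
setGeneric("truthSomas", function(object) standardGeneric("truthSomas"))

#' @rdname truthSomas
#' @export
setMethod("truthSomas", "GroundTruthSet", function(object) object@somas)

#' Region name lookup table
#' @param object a [RegionLabelVolume-class]
#' @export
setGeneric("regionNames", function(object) standardGeneric("regionNames"))

#' @rdname regionNames
#' @export
setMethod("regionNames", "RegionLabelVolume", function(object)
  object@nameTable)

#' Per-region physical volumes
#'
#' Voxel counts and volumes (mm^3) per region, including the "outside"
#' label 0 when present.
#'
#' @param object a [RegionLabelVolume-class]
#' @return data.frame with columns `label`, `region`, `voxels`,
#'   `volume_mm3`.
#' @export
setGeneric("regionVolumes", function(object) standardGeneric("regionVolumes"))

#' @rdname regionVolumes
#' @export
setMethod("regionVolumes", "RegionLabelVolume", function(object) {
  voxvol <- prod(object@voxelSize) * 1e-9 # um^3 -> mm^3
  labs <- sort(unique(as.vector(object@labels)))
  cnt <- tabulate(as.vector(object@labels) + 1L, nbins = max(labs) + 1L)
  data.frame(
    label = labs,
    region = ifelse(labs == 0L, "outside",
                    unname(object@nameTable[as.character(labs)])),
    voxels = cnt[labs + 1L],
    volume_mm3 = cnt[labs + 1L] * voxvol,
    stringsAsFactors = FALSE)
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "ImageStack3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack3D: %d x %d x %d voxels @ %s um, origin (%s) um\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
  cat(sprintf("  intensity range [%s, %s]\n",
              format(min(object@voxels)), format(max(object@voxels))))
})

setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryMask3D: %d x %d x %d voxels @ %s um, %d foreground\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x "),
              sum(object@voxels)))
})

setMethod("show", "RegionLabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("RegionLabelVolume: %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(object@nameTable)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec\n")
  cat(sprintf("  extents %s um, voxels %s um\n",
              paste(format(object@shapeUm), collapse = " x "),
              paste(format(object@voxelSizeUm), collapse = " x ")))
  if (is.na(object@nSomas))
    cat(sprintf("  density %g somas/mm^3\n", object@density))
  else cat(sprintf("  %d somas\n", object@nSomas))
  cat(sprintf("  semi-axes (%s) um +/- %g%%, min separation %g um\n",
              paste(format(object@radiusMeanUm), collapse = ", "),
              100 * object@radiusJitter, object@minSeparationUm))
  cat(sprintf("  axial pairs %g%%, neurites %g /mm^3, seed %d\n",
              100 * object@axialPairFraction, object@neuriteDensity,
              object@seed))
})

setMethod("show", "GroundTruthSet", function(object) {
  cat(sprintf("GroundTruthSet: %d somas (%d in axial pairs)\n",
              nrow(object@somas), sum(!is.na(object@somas$pair))))
})

setMethod("show", "BlockLayout", function(object) {
  cat(sprintf("BlockLayout: %d blocks of %s um, halo %g um\n",
              nrow(object@blocks),
              paste(format(object@blockSizeUm), collapse = " x "),
              object@haloUm))
})

setMethod("show", "SomaMask", function(object) {
  cat(sprintf("SomaMask: %d voxels @ %s um\n", length(object@indices),
              paste(format(object@voxelSize), collapse = " x ")))
})

# ---- coordinate helpers (internal) -----------------------------------------

# um coordinates (n x 3 matrix) -> 1-based voxel indices under the
# nearest-centre half-open ownership rule.
.umToVoxel <- function(xyz, voxelSize, origin) {
  xyz <- matrix(xyz, ncol = 3)
  idx <- sweep(xyz, 2, origin)
  idx <- sweep(idx, 2, voxelSize, "/")
  matrix(as.integer(floor(idx + 0.5)), ncol = 3) + 1L
}

# 1-based voxel indices (n x 3) -> um coordinates of voxel centres.
.voxelToUm <- function(ijk, voxelSize, origin) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, voxelSize, "*"), 2, origin, "+")
}

# 1-based linear indices -> n x 3 voxel indices.
.linToVox <- function(lin, dims) {
  arrayInd(lin, .dim = dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
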