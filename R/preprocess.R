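# Foreground extraction (binarization + erosion + small-component removal)
# and block decomposition of large volumes.

# Otsu threshold on a 256-bin histogram of the full stack. Returns the
# intensity t such that voxels >= t are foreground.
.otsuThreshold <- function(v, nbins = 256L) {
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo)
    stop("Otsu binarization impossible: stack has constant intensity")
  counts <- cpp_hist_counts(v, as.numeric(lo), as.numeric(hi), nbins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nbins) - 0.5))
  muT <- mu[nbins]
  sigma2 <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  k <- which.max(sigma2) # first bin index maximizing between-class variance
  lo + (hi - lo) * k / nbins
}

#' Binarize an image stack
#'
#' Foreground is every voxel with intensity `>= threshold`. With
#' `method = "otsu"` the threshold maximizes the between-class variance of
#' the full-stack 256-bin histogram; with `method = "fixed"` it must be
#' supplied.
#'
#' @param stack an [ImageStack3D-class].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold, required for `method = "fixed"`.
#' @return A [BinaryMask3D-class]; the chosen threshold is attached as
#'   `attr(mask, "threshold")` on the voxel array's wrapper via the
#'   returned object's `threshold` attribute.
#' @examples
#' st <- ImageStack3D(array(c(10L, 200L), dim = c(4, 4, 2)), c(1, 1, 2))
#' mask <- binarize(st, "otsu")
#' sum(voxels(mask))
#' @export
binarize <- function(stack, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    thr <- threshold
  } else {
    thr <- .otsuThreshold(stack@voxels)
  }
  m <- stack@voxels >= thr
  out <- BinaryMask3D(m, stack@voxelSize, stack@origin)
  attr(out, "threshold") <- thr
  out
}

#' Morphological erosion of a binary mask
#'
#' Erosion with a 6-connected (face-neighbour) structuring element applied
#' `repetitions` times; voxels outside the array count as background. This
#' is a voxel-space operation: on anisotropic grids one repetition removes
#' one voxel shell per axis regardless of physical pitch.
#'
#' @param mask a [BinaryMask3D-class].
#' @param repetitions number of erosion passes (>= 0; 0 is the identity).
#' @return The eroded [BinaryMask3D-class].
#' @export
erodeMask <- function(mask, repetitions = 1L) {
  stopifnot(repetitions >= 0)
  if (repetitions == 0) return(mask)
  d <- dim(mask@voxels)
  v <- cpp_erode6(mask@voxels, d, as.integer(repetitions))
  dim(v) <- d
  BinaryMask3D(v, mask@voxelSize, mask@origin)
}

#' Extract the foreground of a stack
#'
#' Binarization, erosion, then removal of 26-connected components smaller
#' than `min_component_voxels`. This is the preprocessing in front of the
#' soma localizer: erosion detaches thin neurites, and the size filter
#' removes residual specks.
#'
#' @inheritParams binarize
#' @param erosion_reps number of 6-connected erosion passes.
#' @param min_component_voxels components with fewer voxels are dropped
#'   (0 disables the filter).
#' @return A [BinaryMask3D-class].
#' @export
extractForeground <- function(stack, method = c("otsu", "fixed"),
                              threshold = NULL, erosion_reps = 1L,
                              min_component_voxels = 20L) {
  mask <- binarize(stack, method, threshold)
  mask <- erodeMask(mask, erosion_reps)
  if (min_component_voxels > 0 && any(mask@voxels)) {
    d <- dim(mask@voxels)
    lab <- cpp_label26(mask@voxels, d)
    nl <- max(lab)
    if (nl > 0) {
      sizes <- tabulate(lab, nbins = nl)
      keep <- sizes >= min_component_voxels
      v <- lab > 0L
      v[v] <- keep[lab[lab > 0L]]
      dim(v) <- d
      mask <- BinaryMask3D(v, mask@voxelSize, mask@origin)
    }
  }
  mask
}

#' Parameter bag for foreground extraction
#'
#' @inheritParams extractForeground
#' @return A classed list consumed by [locateSomas()] and friends.
#' @export
preprocessConfig <- function(method = "otsu", threshold = NULL,
                             erosion_reps = 1L, min_component_voxels = 20L) {
  structure(list(method = method, threshold = threshold,
                 erosion_reps = as.integer(erosion_reps),
                 min_component_voxels = as.integer(min_component_voxels)),
            class = "preprocessConfig")
}

#' Decompose a volume into processing blocks
#'
#' Half-open core tiles (in voxel space, nominally `block_size_um` each)
#' that partition the grid exactly once, plus padded regions extending each
#' core by `halo_um` and clipped at the volume bounds. The default halo of
#' 40 um is twice the largest expected soma diameter, so a soma straddling
#' a seam is wholly visible to the block that owns its centre.
#'
#' @param stack an [ImageStack3D-class].
#' @param block_size_um numeric(3) nominal block size in micrometres.
#' @param halo_um scalar halo margin in micrometres.
#' @return A [BlockLayout-class].
#' @examples
#' st <- ImageStack3D(array(0L, dim = c(64, 32, 16)), c(1, 1, 2))
#' decomposeBlocks(st, block_size_um = c(32, 32, 32), halo_um = 4)
#' @export
decomposeBlocks <- function(stack, block_size_um = c(512, 512, 512),
                            halo_um = 40) {
  stopifnot(all(block_size_um > 0), halo_um >= 0)
  d <- dim(stack@voxels)
  v <- stack@voxelSize
  bs <- as.integer(round(block_size_um / v))
  if (any(bs < 1))
    stop("block size smaller than one voxel")
  hv <- as.integer(ceiling(halo_um / v))
  ranges <- lapply(1:3, function(a) {
    starts <- seq.int(0L, d[a] - 1L, by = bs[a])
    ends <- pmin(starts + bs[a], d[a])
    cbind(lo = starts, hi = ends,
          plo = pmax(0L, starts - hv[a]), phi = pmin(d[a], ends + hv[a]))
  })
  g <- expand.grid(x = seq_len(nrow(ranges[[1]])),
                   y = seq_len(nrow(ranges[[2]])),
                   z = seq_len(nrow(ranges[[3]])))
  blocks <- data.frame(
    block = seq_len(nrow(g)),
    ix0 = ranges[[1]][g$x, "lo"], ix1 = ranges[[1]][g$x, "hi"],
    iy0 = ranges[[2]][g$y, "lo"], iy1 = ranges[[2]][g$y, "hi"],
    iz0 = ranges[[3]][g$z, "lo"], iz1 = ranges[[3]][g$z, "hi"],
    px0 = ranges[[1]][g$x, "plo"], px1 = ranges[[1]][g$x, "phi"],
    py0 = ranges[[2]][g$y, "plo"], py1 = ranges[[2]][g$y, "phi"],
    pz0 = ranges[[3]][g$z, "plo"], pz1 = ranges[[3]][g$z, "phi"])
  new("BlockLayout", blockSizeUm = as.numeric(block_size_um),
      haloUm = as.numeric(halo_um), blocks = blocks, dims = d,
      voxelSize = v, origin = stack@origin)
}
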