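#' Describe a synthetic labelled-soma phantom
#'
#' Builds a validated [PhantomSpec-class]. The defaults emulate a
#' fluorescently labelled interneuron population imaged at anisotropic
#' resolution: ellipsoidal somas with semi-axes drawn around 6 x 5 x 4 um
#' (the qualitative 3-8 um range of cortical interneuron cell bodies), a
#' density of 10,000 somas/mm^3 (neocortex-like), a 12 um centre-to-centre
#' exclusion distance, a small fraction of disjoint z-aligned soma pairs
#' (the configuration that planar counting merges), sparse neurite clutter,
#' bright somas (200) over a dim background (10) with additive Gaussian
#' noise (sigma 5) on an 8-bit scale.
#'
#' @param shape_um numeric(3), physical extents in micrometres.
#' @param voxel_size_um numeric(3), voxel pitch in micrometres.
#' @param n_somas integer soma count; leave `NA` to derive it from
#'   `density`.
#' @param density somas per cubic millimetre (used when `n_somas` is NA).
#' @param radius_mean_um numeric(3), mean semi-axes a >= b >= c in
#'   micrometres.
#' @param radius_jitter fractional uniform jitter on each semi-axis.
#' @param min_separation_um centre-to-centre exclusion distance (um);
#'   designated axial pairs are exempt from it with respect to each other.
#' @param axial_pair_fraction fraction of somas placed as disjoint z-aligned
#'   pairs.
#' @param neurite_density neurite tubes per cubic millimetre.
#' @param soma_intensity,background_intensity,noise_sigma grayscale levels.
#' @param seed integer RNG seed; the same spec always renders the same
#'   phantom.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(shape_um = c(100, 100, 60), n_somas = 5, seed = 1)
#' spec
#' @export
phantomSpec <- function(shape_um = c(256, 256, 256),
                        voxel_size_um = c(1, 1, 2),
                        n_somas = NA_integer_,
                        density = 10000,
                        radius_mean_um = c(6, 5, 4),
                        radius_jitter = 0.15,
                        min_separation_um = 12,
                        axial_pair_fraction = 0.1,
                        neurite_density = 300,
                        soma_intensity = 200,
                        background_intensity = 10,
                        noise_sigma = 5,
                        seed) {
  obj <- new("PhantomSpec",
    shapeUm = as.numeric(shape_um),
    voxelSizeUm = as.numeric(voxel_size_um),
    nSomas = as.integer(n_somas),
    density = as.numeric(density),
    radiusMeanUm = as.numeric(radius_mean_um),
    radiusJitter = as.numeric(radius_jitter),
    minSeparationUm = as.numeric(min_separation_um),
    axialPairFraction = as.numeric(axial_pair_fraction),
    neuriteDensity = as.numeric(neurite_density),
    somaIntensity = as.numeric(soma_intensity),
    backgroundIntensity = as.numeric(background_intensity),
    noiseSigma = as.numeric(noise_sigma),
    seed = as.integer(seed))
  validObject(obj)
  obj
}

# Draw jittered semi-axes, sorted a >= b >= c.
.drawSemiAxes <- function(spec) {
  ax <- spec@radiusMeanUm *
    (1 + stats::runif(3, -spec@radiusJitter, spec@radiusJitter))
  sort(ax, decreasing = TRUE)
}

# Rejection-sample soma centres: singles plus disjoint z-aligned pairs.
# Returns the truth data.frame. Errors (naming the achieved count) if the
# attempt budget of 10000 * n placements is exhausted.
.placeSomas <- function(spec, n) {
  ext <- spec@shapeUm
  minsep2 <- spec@minSeparationUm^2
  npair <- floor(spec@axialPairFraction * n / 2)
  rows <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 3)
  pairof <- integer(0)

  okSep <- function(p, exempt = 0L) {
    if (nrow(placed) == 0) return(TRUE)
    d2 <- colSums((t(placed) - p)^2)
    if (exempt > 0L) d2[exempt] <- Inf
    all(d2 >= minsep2)
  }

  budget <- 10000 * max(n, 1)
  attempts <- 0
  k <- 0

  samplePoint <- function(axes, zmaxExtra = 0) {
    lo <- c(axes[1], axes[1], axes[3])
    hi <- ext - c(axes[1], axes[1], axes[3] + zmaxExtra)
    if (any(hi < lo)) return(NULL)
    stats::runif(3, lo, hi)
  }

  # axial pairs first: base soma plus a partner straight above in z with a
  # surface gap of 2-6 um (disjoint, but overlapping in any z-projection)
  for (p in seq_len(npair)) {
    repeat {
      attempts <- attempts + 1
      if (attempts > budget)
        stop(sprintf(
          "phantom placement failed: placed %d of %d somas within the attempt budget",
          k, n))
      ax1 <- .drawSemiAxes(spec)
      ax2 <- .drawSemiAxes(spec)
      gap <- ax1[3] + ax2[3] + stats::runif(1, 2, 6)
      c1 <- samplePoint(ax1, zmaxExtra = gap)
      if (is.null(c1)) next
      c2 <- c1 + c(0, 0, gap)
      if (c2[3] > ext[3] - ax2[3]) next
      if (!okSep(c1) || !okSep(c2)) next
      # partner exempt from separation with its base by construction
      th1 <- stats::runif(1, 0, pi)
      th2 <- stats::runif(1, 0, pi)
      rows[[k + 1]] <- c(c1, ax1, th1, p)
      rows[[k + 2]] <- c(c2, ax2, th2, p)
      placed <- rbind(placed, c1, c2)
      k <- k + 2
      break
    }
  }

  while (k < n) {
    attempts <- attempts + 1
    if (attempts > budget)
      stop(sprintf(
        "phantom placement failed: placed %d of %d somas within the attempt budget",
        k, n))
    ax <- .drawSemiAxes(spec)
    p <- samplePoint(ax)
    if (is.null(p))
      stop("phantom extents too small for the requested soma size")
    if (!okSep(p)) next
    th <- stats::runif(1, 0, pi)
    rows[[k + 1]] <- c(p, ax, th, NA_real_)
    placed <- rbind(placed, p)
    k <- k + 1
  }

  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 8)
  data.frame(id = seq_len(nrow(m)),
             x_um = m[, 1], y_um = m[, 2], z_um = m[, 3],
             a_um = m[, 4], b_um = m[, 5], c_um = m[, 6],
             theta = m[, 7], pair = m[, 8])
}

# Place somas uniformly inside atlas regions at given per-region densities.
.placeSomasInRegions <- function(spec, atlas, regionDensities) {
  rv <- regionVolumes(atlas)
  rv <- rv[rv$label != 0L, , drop = FALSE]
  if (length(regionDensities) != nrow(rv))
    stop("regionDensities must give one density per nonzero atlas label")
  dims <- dim(atlas@labels)
  minsep2 <- spec@minSeparationUm^2
  ext <- spec@shapeUm
  rows <- list()
  placed <- matrix(numeric(0), ncol = 3)
  k <- 0
  for (ri in seq_len(nrow(rv))) {
    lab <- rv$label[ri]
    nTarget <- round(regionDensities[ri] * rv$volume_mm3[ri])
    cand <- which(atlas@labels == lab)
    budget <- 10000 * max(nTarget, 1)
    attempts <- 0
    got <- 0
    while (got < nTarget) {
      attempts <- attempts + 1
      if (attempts > budget)
        stop(sprintf(
          "phantom placement failed: placed %d of %d somas in region %s",
          got, nTarget, rv$region[ri]))
      ax <- .drawSemiAxes(spec)
      vi <- .linToVox(cand[sample.int(length(cand), 1)], dims)
      p <- .voxelToUm(vi, atlas@voxelSize, atlas@origin)[1, ] +
        stats::runif(3, -0.5, 0.5) * atlas@voxelSize
      lo <- c(ax[1], ax[1], ax[3])
      if (any(p < lo) || any(p > ext - lo)) next
      if (nrow(placed) > 0 && any(colSums((t(placed) - p)^2) < minsep2)) next
      th <- stats::runif(1, 0, pi)
      rows[[k + 1]] <- c(p, ax, th)
      placed <- rbind(placed, p)
      k <- k + 1
      got <- got + 1
    }
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), ncol = 7)
  data.frame(id = seq_len(nrow(m)),
             x_um = m[, 1], y_um = m[, 2], z_um = m[, 3],
             a_um = m[, 4], b_um = m[, 5], c_um = m[, 6],
             theta = m[, 7], pair = NA_real_)
}

# Random-walk neurite tubes, returned as a sphere list (x, y, z, r).
.drawNeurites <- function(spec) {
  volMm3 <- prod(spec@shapeUm) * 1e-9
  nTube <- round(spec@neuriteDensity * volMm3)
  if (nTube == 0) return(matrix(numeric(0), ncol = 4))
  ext <- spec@shapeUm
  out <- list()
  for (t in seq_len(nTube)) {
    r <- stats::runif(1, 0.5, 1)
    p <- stats::runif(3, 0, ext)
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    len <- stats::runif(1, 40, 100)
    nstep <- ceiling(len)
    pts <- matrix(NA_real_, nstep, 4)
    for (s in seq_len(nstep)) {
      pts[s, ] <- c(p, r)
      d <- d + stats::rnorm(3, sd = 0.15)
      d <- d / sqrt(sum(d^2))
      p <- pmin(pmax(p + d, 0), ext)
    }
    out[[t]] <- pts
  }
  do.call(rbind, out)
}

#' Generate a synthetic 3D phantom with known soma ground truth
#'
#' Renders the scene described by a [PhantomSpec-class]: ellipsoidal somas
#' (anti-aliased at the boundary by 2x2x2 partial-volume subsampling),
#' neurites as constant-radius random-walk tubes at an intensity midway
#' between background and soma, additive Gaussian noise, and clipping to
#' the 8-bit range. The same spec (including seed) always produces a
#' bit-identical stack and truth set.
#'
#' When `atlas` and `region_densities` are supplied, somas are placed
#' uniformly inside each labelled region at the stated density
#' (cells/mm^3) instead of uniformly over the whole volume; the realized
#' per-region truth is attached as `attr(truth, "regionTruth")`.
#'
#' @param spec a [PhantomSpec-class].
#' @param atlas optional [RegionLabelVolume-class] on the same grid.
#' @param region_densities optional numeric vector of somas/mm^3, one per
#'   nonzero atlas label (in label order).
#' @return list with elements `stack` ([ImageStack3D-class]) and `truth`
#'   ([GroundTruthSet-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape_um = c(80, 80, 40), n_somas = 2,
#'                                   neurite_density = 0, seed = 7))
#' ph$stack
#' truthSomas(ph$truth)
#' @export
generatePhantom <- function(spec, atlas = NULL, region_densities = NULL) {
  validObject(spec)
  dims <- pmax(1L, as.integer(round(spec@shapeUm / spec@voxelSizeUm)))
  n <- if (!is.na(spec@nSomas)) spec@nSomas
       else as.integer(round(spec@density * prod(spec@shapeUm) * 1e-9))

  withr::with_seed(spec@seed, {
    if (!is.null(atlas)) {
      truth <- .placeSomasInRegions(spec, atlas, region_densities)
    } else {
      truth <- .placeSomas(spec, n)
    }
    tubes <- .drawNeurites(spec)
    somaMat <- as.matrix(truth[, c("x_um", "y_um", "z_um",
                                   "a_um", "b_um", "c_um", "theta")])
    vox <- cpp_render_phantom(
      dims, spec@voxelSizeUm, somaMat,
      tubes, spec@backgroundIntensity, spec@somaIntensity,
      (spec@backgroundIntensity + spec@somaIntensity) / 2,
      spec@noiseSigma, 0, 255)
  })
  dim(vox) <- dims

  truthSet <- new("GroundTruthSet", somas = truth, spec = spec)
  if (!is.null(atlas)) {
    rv <- regionVolumes(atlas)
    rv <- rv[rv$label != 0L, , drop = FALSE]
    vi <- .umToVoxel(as.matrix(truth[, c("x_um", "y_um", "z_um")]),
                     atlas@voxelSize, atlas@origin)
    vlab <- atlas@labels[vi]
    cnt <- vapply(rv$label, function(l) sum(vlab == l), integer(1))
    attr(truthSet@somas, "regionTruth") <- data.frame(
      label = rv$label, region = rv$region, n = cnt,
      volume_mm3 = rv$volume_mm3, density = cnt / rv$volume_mm3)
  }
  list(stack = ImageStack3D(vox, spec@voxelSizeUm), truth = truthSet)
}

#' Generate a synthetic region label volume
#'
#' Partitions the voxel grid into `n_regions` contiguous slabs along the
#' longest axis (labels 1..n, covering every voxel), a stand-in for a
#' manually contoured anatomical label volume.
#'
#' @param shape_um numeric(3), physical extents in micrometres.
#' @param voxel_size_um numeric(3), voxel pitch in micrometres.
#' @param n_regions number of regions (>= 1).
#' @param seed integer seed (kept for interface symmetry; the slab
#'   partition itself is deterministic).
#' @return A [RegionLabelVolume-class] with regions named `R1..Rn`.
#' @examples
#' atl <- generateRegionAtlas(c(100, 100, 100), c(1, 1, 2), 2)
#' regionVolumes(atl)
#' @export
generateRegionAtlas <- function(shape_um, voxel_size_um, n_regions,
                                seed = 1L) {
  stopifnot(n_regions >= 1)
  dims <- pmax(1L, as.integer(round(shape_um / voxel_size_um)))
  axis <- which.max(shape_um)
  if (dims[axis] < n_regions)
    stop("voxel grid too small for the requested number of regions")
  # near-equal slab thicknesses along the longest axis
  bounds <- round(seq(0, dims[axis], length.out = n_regions + 1))
  sizes <- diff(bounds)
  line <- rep(seq_len(n_regions), times = sizes)
  labels <- array(0L, dim = dims)
  if (axis == 1) labels[] <- line
  else if (axis == 2) labels[] <- rep(line, each = dims[1])
  else labels[] <- rep(line, each = dims[1] * dims[2])
  names <- sprintf("R%d", seq_len(n_regions))
  names(names) <- as.character(seq_len(n_regions))
  RegionLabelVolume(labels, voxel_size_um, names)
}

#' Write / read a ground-truth soma table as CSV
#'
#' Column layout `id,x_um,y_um,z_um,a_um,b_um,c_um` (orientation and pair
#' bookkeeping columns are appended when present).
#'
#' @param truth a [GroundTruthSet-class] or its soma data.frame.
#' @param path file path.
#' @return `readTruthCsv` returns the soma data.frame.
#' @export
writeTruthCsv <- function(truth, path) {
  df <- if (is(truth, "GroundTruthSet")) truthSomas(truth) else truth
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTruthCsv
#' @export
readTruthCsv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("truth CSV must have columns id,x_um,y_um,z_um")
  df
}
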