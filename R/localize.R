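# Sparse L1 ball-superposition soma localization: candidate seeding on the
# anisotropy-aware distance transform, non-negative LASSO over a dictionary
# of ball indicators, greedy non-maximum suppression, block-wise execution,
# and the planar (z-projection) counting emulation used for comparison.

#' Configuration of the L1 ball-superposition fit
#'
#' @param radius_set_um ascending candidate ball radii in micrometres.
#' @param lambda L1 penalty weight; `NULL` picks `0.1 * max|phi' f|`, a
#'   scale-relative default.
#' @param weight_min acceptance threshold on the fitted coefficient.
#' @param merge_dist_um minimum centre separation enforced by non-maximum
#'   suppression.
#' @param max_iter maximum proximal-gradient iterations.
#' @param tol relative objective-change stopping tolerance.
#' @return A classed parameter list.
#' @export
l1Config <- function(radius_set_um = c(2, 3, 4, 5, 6, 8, 10),
                     lambda = NULL, weight_min = 0.2, merge_dist_um = 8,
                     max_iter = 500L, tol = 1e-4) {
  stopifnot(all(radius_set_um > 0), !is.unsorted(radius_set_um),
            max_iter >= 1, tol > 0, weight_min >= 0)
  if (!is.null(lambda)) stopifnot(lambda >= 0)
  structure(list(radius_set_um = as.numeric(radius_set_um), lambda = lambda,
                 weight_min = weight_min, merge_dist_um = merge_dist_um,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "l1Config")
}

.emptyDetections <- function() {
  data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
             z_um = numeric(0), radius_um = numeric(0), weight = numeric(0),
             block = integer(0))
}

#' Seed candidate soma centres from a foreground mask
#'
#' Candidates are the 26-neighbourhood local maxima of the
#' anisotropy-aware Euclidean distance transform of the mask (distances in
#' micrometres), with maxima closer than `merge_dist_um` merged to their
#' centroid. Every foreground component yields at least one candidate (its
#' interior distance maximum).
#'
#' @param mask a [BinaryMask3D-class].
#' @param merge_dist_um maxima closer than this are merged (um).
#' @return matrix with columns `x_um`, `y_um`, `z_um`, ordered
#'   lexicographically; zero rows for an empty mask.
#' @export
seedCandidates <- function(mask, merge_dist_um = 2) {
  d <- dim(mask@voxels)
  if (!any(mask@voxels))
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x_um", "y_um", "z_um"))))
  d2 <- cpp_edt_sq(mask@voxels, d, mask@voxelSize)
  idx0 <- cpp_local_maxima(d2, d)
  vi <- .linToVox(idx0 + 1L, d)
  pts <- .voxelToUm(vi, mask@voxelSize, mask@origin)
  cl <- cpp_merge_points(pts, merge_dist_um)
  cx <- tapply(pts[, 1], cl, mean)
  cy <- tapply(pts[, 2], cl, mean)
  cz <- tapply(pts[, 3], cl, mean)
  out <- cbind(x_um = as.numeric(cx), y_um = as.numeric(cy),
               z_um = as.numeric(cz))
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

#' Fit the sparse L1 ball-superposition model
#'
#' Builds one unit-normalized ball-indicator atom per (candidate, radius)
#' pair on the anisotropic grid and solves
#' \deqn{\min_{w \ge 0} \tfrac12 \| \Sigma_i w_i \phi_i - f \|^2 +
#'   \lambda \|w\|_1}
#' with `f` the binary foreground, by proximal-gradient descent (ISTA, step
#' `1/L` with `L` the largest row sum of the absolute Gram matrix) with
#' non-negativity projection. Each candidate keeps its best-weight radius;
#' coefficients below `weight_min` are discarded; surviving centres undergo
#' greedy weight-descending non-maximum suppression at `merge_dist_um`
#' (ties broken by lexicographic centre order).
#'
#' @param stack the parent [ImageStack3D-class] (checked for finite
#'   intensities).
#' @param mask the extracted foreground [BinaryMask3D-class].
#' @param candidates matrix of candidate centres (columns x/y/z, um), as
#'   returned by [seedCandidates()].
#' @param config an [l1Config()].
#' @param block_id block tag stored with each detection.
#' @return data.frame of detections with columns `id`, `x_um`, `y_um`,
#'   `z_um`, `radius_um`, `weight`, `block`; the per-iteration objective
#'   trace is attached as `attr(, "objective")`.
#' @export
fitL1Model <- function(stack, mask, candidates, config = l1Config(),
                       block_id = NA_integer_) {
  if (is.double(stack@voxels) && any(!is.finite(stack@voxels)))
    stop("stack contains non-finite intensities")
  if (nrow(candidates) == 0) return(.emptyDetections())
  d <- dim(mask@voxels)
  vsz <- mask@voxelSize
  org <- mask@origin
  radii <- config$radius_set_um
  nr <- length(radii)
  nc <- nrow(candidates)
  natoms <- nc * nr

  centersRel <- sweep(as.matrix(candidates[, 1:3, drop = FALSE]), 2, org)
  at <- cpp_ball_atoms(d, vsz, centersRel, radii)
  atom <- at$atom
  vox1 <- at$vox + 1L
  m <- tabulate(atom, nbins = natoms)
  rows <- sort(unique(vox1))
  ri <- match(vox1, rows)
  A <- Matrix::sparseMatrix(i = ri, j = atom, x = 1 / sqrt(m[atom]),
                            dims = c(length(rows), natoms))
  f <- as.numeric(mask@voxels[rows])

  Atf <- as.numeric(Matrix::crossprod(A, f))
  G <- Matrix::crossprod(A)
  lambda <- config$lambda %||% (0.1 * max(abs(Atf)))
  L <- max(Matrix::rowSums(abs(G)))
  step <- 1 / L
  ff <- sum(f)

  w <- numeric(natoms)
  Gw <- numeric(natoms)
  objs <- numeric(0)
  prev <- 0.5 * ff # objective at w = 0
  for (it in seq_len(config$max_iter)) {
    w <- pmax(0, w - step * (Gw - Atf + lambda))
    Gw <- as.numeric(G %*% w)
    o <- 0.5 * (sum(w * Gw) - 2 * sum(w * Atf) + ff) + lambda * sum(w)
    objs <- c(objs, o)
    if (abs(prev - o) <= config$tol * max(abs(prev), 1e-12)) break
    prev <- o
  }

  # best radius per candidate, then acceptance threshold
  W <- matrix(w, nrow = nr)
  bestj <- apply(W, 2, which.max)
  bestw <- W[cbind(bestj, seq_len(nc))]
  keep <- which(bestw >= config$weight_min)
  if (length(keep) == 0) {
    out <- .emptyDetections()
    attr(out, "objective") <- objs
    return(out)
  }

  cand <- candidates[keep, , drop = FALSE]
  wt <- bestw[keep]
  rad <- radii[bestj[keep]]

  # greedy non-maximum suppression, weight descending, lexicographic ties
  ord <- order(-wt, cand[, 1], cand[, 2], cand[, 3])
  acc <- integer(0)
  md2 <- config$merge_dist_um^2
  for (i in ord) {
    p <- cand[i, ]
    if (length(acc) == 0 ||
        all(colSums((t(cand[acc, , drop = FALSE]) - p)^2) >= md2))
      acc <- c(acc, i)
  }
  acc <- sort(acc)
  out <- data.frame(id = seq_along(acc),
                    x_um = cand[acc, 1], y_um = cand[acc, 2],
                    z_um = cand[acc, 3], radius_um = rad[acc],
                    weight = wt[acc],
                    block = rep(as.integer(block_id), length(acc)))
  rownames(out) <- NULL
  attr(out, "objective") <- objs
  out
}

#' Locate somas in a whole volume
#'
#' Foreground extraction, candidate seeding and the L1 superposition fit,
#' in one call. Deterministic: no randomness is involved in fitting.
#'
#' @param stack an [ImageStack3D-class].
#' @param preprocess a [preprocessConfig()].
#' @param l1 an [l1Config()].
#' @param block_id block tag stored with each detection.
#' @return data.frame of detections (see [fitL1Model()]).
#' @export
locateSomas <- function(stack, preprocess = preprocessConfig(),
                        l1 = l1Config(), block_id = NA_integer_) {
  mask <- extractForeground(stack, preprocess$method, preprocess$threshold,
                            preprocess$erosion_reps,
                            preprocess$min_component_voxels)
  cand <- seedCandidates(mask)
  fitL1Model(stack, mask, cand, l1, block_id = block_id)
}

#' Locate somas block by block
#'
#' Runs the whole-volume pipeline on every padded block of a
#' [BlockLayout-class] and keeps only detections whose centre voxel lies in
#' the block's half-open core, which assigns every seam-straddling soma to
#' exactly one block. Coordinates are global micrometres.
#'
#' @param stack an [ImageStack3D-class].
#' @param layout a [BlockLayout-class] covering the stack (default: blocks
#'   of 512 um with a 40 um halo).
#' @param preprocess a [preprocessConfig()].
#' @param l1 an [l1Config()].
#' @return data.frame of detections with global coordinates and the owning
#'   block id.
#' @export
locateSomasBlockwise <- function(stack, layout = NULL,
                                 preprocess = preprocessConfig(),
                                 l1 = l1Config()) {
  if (is.null(layout)) layout <- decomposeBlocks(stack)
  v <- stack@voxelSize
  org <- stack@origin
  res <- list()
  for (b in seq_len(nrow(layout@blocks))) {
    bl <- layout@blocks[b, ]
    sub <- stack@voxels[(bl$px0 + 1):bl$px1, (bl$py0 + 1):bl$py1,
                        (bl$pz0 + 1):bl$pz1, drop = FALSE]
    substack <- ImageStack3D(sub, v,
                             origin = org + c(bl$px0, bl$py0, bl$pz0) * v)
    det <- tryCatch(locateSomas(substack, preprocess, l1, block_id = b),
                    error = function(e) {
                      if (grepl("constant intensity", conditionMessage(e)))
                        .emptyDetections()
                      else stop(e)
                    })
    if (nrow(det) == 0) next
    vi <- .umToVoxel(as.matrix(det[, c("x_um", "y_um", "z_um")]), v, org) - 1L
    own <- vi[, 1] >= bl$ix0 & vi[, 1] < bl$ix1 &
           vi[, 2] >= bl$iy0 & vi[, 2] < bl$iy1 &
           vi[, 3] >= bl$iz0 & vi[, 3] < bl$iz1
    det <- det[own, , drop = FALSE]
    if (nrow(det) == 0) next
    det$block <- rep(b, nrow(det))
    res[[length(res) + 1]] <- det
  }
  out <- if (length(res)) do.call(rbind, res) else .emptyDetections()
  if (nrow(out)) out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Count cells detected in the full 3D volume
#'
#' @param detections a detection data.frame.
#' @return integer count.
#' @export
countCells3D <- function(detections) {
  nrow(detections)
}

#' Planar (z-projection) cell counting
#'
#' Emulates traditional counting in histological sections: the stack is
#' partitioned into consecutive z-slabs of `slab_thickness_um` (the last
#' slab may be thinner), each slab is maximum-intensity-projected, and a 2D
#' analogue of the pipeline (2D Otsu, 2D erosion, 2D distance-transform
#' maxima merged at `merge_dist_um`) counts cells per projection; the
#' total over slabs is returned. Axially aligned somas inside one slab
#' merge in the projection and are counted once — the planar bias that
#' full-3D counting avoids.
#'
#' @param stack an [ImageStack3D-class].
#' @param slab_thickness_um slab thickness in micrometres (>= one z-step).
#' @param method,threshold binarization per slab (a constant-intensity
#'   projection yields zero cells rather than an error).
#' @param erosion_reps 2D erosion passes (4-connected).
#' @param min_component_px minimum 2D component size in pixels.
#' @param merge_dist_um merge distance for 2D distance-transform maxima.
#' @return integer total count over all slabs.
#' @export
countCells2DProjection <- function(stack, slab_thickness_um = 50,
                                   method = "otsu", threshold = NULL,
                                   erosion_reps = 1L, min_component_px = 20L,
                                   merge_dist_um = 8) {
  stopifnot(slab_thickness_um > 0)
  d <- dim(stack@voxels)
  v <- stack@voxelSize
  nzSlab <- floor(slab_thickness_um / v[3])
  if (nzSlab < 1)
    stop("slab thickness is smaller than one z-step")
  starts <- seq.int(1L, d[3], by = nzSlab)
  total <- 0L
  for (s in starts) {
    zidx <- s:min(s + nzSlab - 1L, d[3])
    mip <- Reduce(pmax, lapply(zidx, function(z) stack@voxels[, , z]))
    if (max(mip) <= min(mip)) next # featureless slab: nothing to count
    st2 <- ImageStack3D(array(mip, dim = c(d[1], d[2], 1L)), v, stack@origin)
    mask <- extractForeground(st2, method, threshold, erosion_reps,
                              min_component_px)
    cand <- seedCandidates(mask, merge_dist_um = merge_dist_um)
    total <- total + nrow(cand)
  }
  total
}
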