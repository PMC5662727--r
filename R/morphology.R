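# Per-soma segmentation and morphometry: principal-axis radii, surface
# area, volume and brightness of each detected soma.

#' Segment one soma by intensity region growing
#'
#' Grows a 26-connected region from the detection centre, admitting voxels
#' whose intensity is at least `grow_threshold_fraction` times the mean
#' intensity of the 3x3x3 neighbourhood around the centre, and never
#' growing beyond a hard ball of `max_radius_um` around the centre.
#'
#' @param stack an [ImageStack3D-class].
#' @param centre_um numeric(3) soma centre in micrometres (or a one-row
#'   detection data.frame with `x_um`, `y_um`, `z_um`).
#' @param grow_threshold_fraction fraction of the centre-neighbourhood mean
#'   intensity used as the admission threshold.
#' @param max_radius_um hard growth limit in micrometres.
#' @return A [SomaMask-class] of the connected region containing the
#'   centre.
#' @export
segmentSoma <- function(stack, centre_um, grow_threshold_fraction = 0.5,
                        max_radius_um = 15) {
  if (is.data.frame(centre_um))
    centre_um <- as.numeric(centre_um[1, c("x_um", "y_um", "z_um")])
  d <- dim(stack@voxels)
  v <- stack@voxelSize
  org <- stack@origin
  ci <- .umToVoxel(centre_um, v, org)[1, ]
  if (any(ci < 1L) || any(ci > d))
    stop("soma centre lies outside the volume")
  nb <- stack@voxels[max(1, ci[1] - 1):min(d[1], ci[1] + 1),
                     max(1, ci[2] - 1):min(d[2], ci[2] + 1),
                     max(1, ci[3] - 1):min(d[3], ci[3] + 1)]
  thr <- grow_threshold_fraction * mean(nb)
  if (stack@voxels[ci[1], ci[2], ci[3]] < thr)
    stop(sprintf(
      "centre voxel intensity %g is below the growth threshold %g: mislocalized detection",
      stack@voxels[ci[1], ci[2], ci[3]], thr))
  idx0 <- cpp_region_grow(stack@voxels, d, v, ci - 1L, centre_um - org,
                          thr, max_radius_um)
  new("SomaMask", indices = idx0 + 1L, dims = d, voxelSize = v, origin = org)
}

#' Measure soma morphology
#'
#' Principal axes come from the eigendecomposition of the covariance of the
#' mask's voxel-centre coordinates (in micrometres); the longest / shortest
#' radius is half the extent of the mask projected on the first / last
#' principal axis, compensated by half the voxel footprint along that axis.
#' Volume is voxel count times physical voxel volume; surface area counts
#' exposed voxel faces (a deterministic estimator that overestimates smooth
#' surfaces, by up to ~1.5x for spheres at default pitch); brightness is
#' the mean stack intensity over the mask.
#'
#' @param mask a [SomaMask-class] (>= 2 voxels).
#' @param stack the parent [ImageStack3D-class].
#' @param id optional id copied into the output row.
#' @return one-row data.frame with columns `id`, `longest_radius_um`,
#'   `shortest_radius_um`, `average_radius_um`, `radii_ratio`,
#'   `surface_area_um2`, `volume_um3`, `mean_brightness`, `voxel_count`.
#' @export
measureMorphology <- function(mask, stack, id = NA_integer_) {
  n <- length(mask@indices)
  if (n < 2)
    stop("degenerate soma mask (fewer than 2 voxels)")
  v <- mask@voxelSize
  vi <- .linToVox(mask@indices, mask@dims)
  um <- .voxelToUm(vi, v, mask@origin)
  ctr <- colMeans(um)
  cc <- sweep(um, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  # half-extents along principal axes, + half the voxel footprint at each
  # end (voxel centres underestimate the physical extent by one footprint)
  radii <- vapply(1:3, function(k) {
    u <- ev$vectors[, k]
    pr <- cc %*% u
    foot <- sum(abs(u) * v)
    (max(pr) - min(pr) + foot) / 2
  }, numeric(1))
  radii <- sort(radii, decreasing = TRUE)
  vol <- n * prod(v)
  area <- cpp_exposed_area(mask@indices - 1L, mask@dims, v)
  bright <- mean(stack@voxels[mask@indices])
  data.frame(id = id,
             longest_radius_um = radii[1],
             shortest_radius_um = radii[3],
             average_radius_um = mean(radii),
             radii_ratio = radii[1] / radii[3],
             surface_area_um2 = area,
             volume_um3 = vol,
             mean_brightness = bright,
             voxel_count = n)
}

#' Morphometry table for a set of detections
#'
#' Segments and measures every detection; per-soma failures (mislocalized
#' centres, degenerate masks) are reported as warnings and the row is
#' skipped, never aborting the batch.
#'
#' @param stack an [ImageStack3D-class].
#' @param detections detection data.frame (columns `id`, `x_um`, `y_um`,
#'   `z_um`).
#' @param regions optional character vector of region names, one per
#'   detection row.
#' @param grow_threshold_fraction,max_radius_um passed to [segmentSoma()].
#' @return data.frame with one morphometry row per successfully measured
#'   soma, keyed by `id` and `region`.
#' @export
morphologyTable <- function(stack, detections, regions = NULL,
                            grow_threshold_fraction = 0.5,
                            max_radius_um = 15) {
  if (is.null(regions)) regions <- rep(NA_character_, nrow(detections))
  stopifnot(length(regions) == nrow(detections))
  rows <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    rows[[i]] <- tryCatch({
      sm <- segmentSoma(stack, detections[i, ],
                        grow_threshold_fraction, max_radius_um)
      r <- measureMorphology(sm, stack, id = detections$id[i])
      r$region <- regions[i]
      r
    }, error = function(e) {
      warning(sprintf("soma %s skipped: %s", detections$id[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(0), longest_radius_um = numeric(0),
                      shortest_radius_um = numeric(0),
                      average_radius_um = numeric(0),
                      radii_ratio = numeric(0),
                      surface_area_um2 = numeric(0), volume_um3 = numeric(0),
                      mean_brightness = numeric(0), voxel_count = integer(0),
                      region = character(0))
  }
  rownames(out) <- NULL
  out
}
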