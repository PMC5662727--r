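# Region assignment, per-region counts and densities, and standard-format
# I/O: multi-page TIFF stacks with a JSON voxel-size sidecar, soma-only SWC
# files, CSV detection tables, and the end-to-end pipeline driver.

#' Assign detections to atlas regions
#'
#' Each detection receives the label of the voxel containing its centre
#' (nearest-voxel-centre rule with half-open upper boundaries); label 0
#' maps to `"unassigned"`.
#'
#' @param detections detection data.frame with `x_um`, `y_um`, `z_um`.
#' @param atlas a [RegionLabelVolume-class].
#' @return data.frame with columns `id`, `label`, `region`.
#' @export
assignRegions <- function(detections, atlas) {
  d <- dim(atlas@labels)
  if (nrow(detections) == 0)
    return(data.frame(id = integer(0), label = integer(0),
                      region = character(0)))
  vi <- .umToVoxel(as.matrix(detections[, c("x_um", "y_um", "z_um")]),
                   atlas@voxelSize, atlas@origin)
  oob <- vi[, 1] < 1 | vi[, 1] > d[1] | vi[, 2] < 1 | vi[, 2] > d[2] |
         vi[, 3] < 1 | vi[, 3] > d[3]
  if (any(oob))
    stop(sprintf("detection(s) %s outside the atlas grid",
                 paste(detections$id[oob], collapse = ", ")))
  lab <- atlas@labels[vi]
  data.frame(id = detections$id, label = lab,
             region = ifelse(lab == 0L, "unassigned",
                             unname(atlas@nameTable[as.character(lab)])))
}

#' Per-region counts and densities
#'
#' Cell count, physical volume (mm^3) and density (cells/mm^3) per atlas
#' region, the density being count divided by region volume. An
#' `unassigned` row collects label-0 detections and a `total` row sums all
#' counts (its density refers to the whole gridded volume).
#'
#' @param assignment output of [assignRegions()].
#' @param atlas the [RegionLabelVolume-class] used for the assignment.
#' @return data.frame with columns `region`, `label`, `cell_count`,
#'   `volume_mm3`, `density_per_mm3`.
#' @export
regionStats <- function(assignment, atlas) {
  rv <- regionVolumes(atlas)
  regions <- rv[rv$label != 0L, , drop = FALSE]
  counts <- vapply(regions$label,
                   function(l) sum(assignment$label == l), integer(1))
  if (any(counts > 0 & regions$volume_mm3 <= 0))
    stop("zero-volume region with nonzero cell count")
  out <- data.frame(region = regions$region, label = regions$label,
                    cell_count = counts, volume_mm3 = regions$volume_mm3,
                    density_per_mm3 = ifelse(regions$volume_mm3 > 0,
                                             counts / regions$volume_mm3, 0))
  nUn <- sum(assignment$label == 0L)
  vol0 <- sum(rv$volume_mm3[rv$label == 0L])
  out <- rbind(out, data.frame(
    region = "unassigned", label = 0L, cell_count = nUn, volume_mm3 = vol0,
    density_per_mm3 = if (vol0 > 0) nUn / vol0 else 0))
  totVol <- sum(rv$volume_mm3)
  out <- rbind(out, data.frame(
    region = "total", label = NA_integer_,
    cell_count = sum(out$cell_count), volume_mm3 = totVol,
    density_per_mm3 = sum(out$cell_count) / totVol))
  rownames(out) <- NULL
  out
}

#' Write detections as a soma-only SWC file
#'
#' One parentless node per cell: `id 1 x y z radius -1` (type 1 = soma,
#' coordinates in micrometres, three decimal places).
#'
#' @param detections detection data.frame with `id`, `x_um`, `y_um`,
#'   `z_um`, `radius_um`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSWC <- function(detections, path) {
  lines <- c("# soma-only SWC: one parentless type-1 node per cell",
             "# id type x y z radius parent (um)")
  if (nrow(detections) > 0)
    lines <- c(lines, sprintf("%d 1 %.3f %.3f %.3f %.3f -1",
                              as.integer(detections$id), detections$x_um,
                              detections$y_um, detections$z_um,
                              detections$radius_um))
  writeLines(lines, path)
  invisible(path)
}

#' Read a soma-only SWC file
#'
#' @param path SWC file; `#` lines are comments.
#' @return data.frame with columns `id`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`.
#' @export
readSWC <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(i) {
    fields <- strsplit(trimws(raw[lineno[i]]), "\\s+")[[1]]
    if (length(fields) != 7)
      stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                   lineno[i], length(fields)))
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num)))
      stop(sprintf("malformed SWC line %d: non-numeric field", lineno[i]))
    num
  })
  if (length(rows) == 0)
    return(data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), radius_um = numeric(0)))
  m <- do.call(rbind, rows)
  data.frame(id = as.integer(m[, 1]), x_um = m[, 3], y_um = m[, 4],
             z_um = m[, 5], radius_um = m[, 6])
}

#' Write / read detection tables as CSV
#'
#' Column layout `id,x_um,y_um,z_um,radius_um,weight,block`.
#'
#' @param detections detection data.frame.
#' @param path file path.
#' @return `readDetectionsCsv` returns the detection data.frame.
#' @export
writeDetectionsCsv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDetectionsCsv
#' @export
readDetectionsCsv <- function(path) {
  utils::read.csv(path)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-plane; the physical voxel size and origin live in a
#' JSON sidecar next to the TIFF (TIFF pixel data alone cannot carry the
#' anisotropic pitch reliably). Intensities must fit the requested bit
#' depth; the round trip through [readStackTiff()] preserves integer
#' voxels bitwise.
#'
#' @param stack an [ImageStack3D-class] with integer intensities.
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path (default `<path>.json`).
#' @param bits_per_sample 8 or 16.
#' @return the TIFF path, invisibly.
#' @export
writeStackTiff <- function(stack, path, sidecar = paste0(path, ".json"),
                           bits_per_sample = 16L) {
  stopifnot(bits_per_sample %in% c(8L, 16L))
  maxv <- 2^bits_per_sample - 1
  v <- stack@voxels
  if (max(v) > maxv || min(v) < 0)
    stop(sprintf("intensities outside [0, %d]", maxv))
  pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]) / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  jsonlite::write_json(
    list(voxel_size_um = stack@voxelSize, origin_um = stack@origin,
         bits_per_sample = bits_per_sample),
    sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack with its JSON sidecar
#'
#' The sidecar is required: a stack without a stated voxel size is
#' rejected rather than defaulted.
#'
#' @param path TIFF file.
#' @param sidecar JSON sidecar carrying `voxel_size_um` (and optionally
#'   `origin_um`, `bits_per_sample`).
#' @return An [ImageStack3D-class] with integer voxels.
#' @export
readStackTiff <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop(sprintf("missing voxel-size sidecar '%s': refusing to guess a voxel size",
                 sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um))
    stop("sidecar does not state voxel_size_um")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent page shapes in TIFF")
  nx <- shp[2, 1]
  ny <- shp[1, 1]
  vox <- array(0L, dim = c(nx, ny, length(pages)))
  for (z in seq_along(pages)) vox[, , z] <- t(pages[[z]])
  ImageStack3D(vox, meta$voxel_size_um,
               origin = meta$origin_um %||% c(0, 0, 0))
}

#' Run the whole pipeline from a configuration
#'
#' End to end: obtain the stack (from a phantom spec or a TIFF file),
#' extract the foreground, locate somas block-wise, count in 3D and in
#' z-projections, measure morphology, assign regions and compute
#' densities (when an atlas is given), evaluate against ground truth
#' (when available), and write `somas.csv`, `somas.swc`, `morph.csv`,
#' `regions.csv`, `report.json` and `pipeline.log` to `out_dir`. Seeded
#' runs are bit-reproducible; the report carries no timestamps.
#'
#' @param config a YAML file path or an equivalent nested list. Recognised
#'   blocks: `phantom` (arguments of [phantomSpec()]) or `input`
#'   (`stack`/`sidecar` paths), `preprocess`, `l1`, `blocks`
#'   (`size_um`, `halo_um`), `atlas` (`n_regions` or `path`),
#'   `morphology`, `evaluation` (`max_dist_um`),
#'   `slab_thickness_um`, `use_truth`.
#' @param out_dir output directory (created if missing); defaults to
#'   `config$out_dir`.
#' @return invisibly, the report list.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  cat("", file = logf)
  note <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    note("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  stack <- stage("input", {
    if (!is.null(config$phantom)) {
      spec <- do.call(phantomSpec, config$phantom)
      ph <- generatePhantom(spec)
      truth <- ph$truth
      ph$stack
    } else if (!is.null(config$input)) {
      readStackTiff(config$input$stack,
                    config$input$sidecar %||%
                      paste0(config$input$stack, ".json"))
    } else stop("config needs a 'phantom' or 'input' block")
  })
  note("stack %s voxels", paste(dim(stack), collapse = "x"))

  pp <- do.call(preprocessConfig, config$preprocess %||% list())
  l1 <- do.call(l1Config, config$l1 %||% list())
  blocksCfg <- config$blocks %||% list()
  layout <- decomposeBlocks(stack,
                            block_size_um = blocksCfg$size_um %||%
                              c(512, 512, 512),
                            halo_um = blocksCfg$halo_um %||% 40)

  det <- stage("locate", locateSomasBlockwise(stack, layout, pp, l1))
  note("%d detections", nrow(det))

  n2d <- stage("planar_count", countCells2DProjection(
    stack, slab_thickness_um = config$slab_thickness_um %||% 50,
    method = pp$method, threshold = pp$threshold,
    erosion_reps = pp$erosion_reps, merge_dist_um = l1$merge_dist_um))

  atlas <- NULL
  regions <- NULL
  if (!is.null(config$atlas)) {
    atlas <- stage("atlas", {
      if (!is.null(config$atlas$path)) {
        st <- readStackTiff(config$atlas$path)
        nm <- config$atlas$names %||%
          sprintf("R%d", seq_len(max(st@voxels)))
        names(nm) <- as.character(seq_along(nm))
        RegionLabelVolume(voxels(st), voxelSize(st), nm)
      } else {
        generateRegionAtlas(dim(stack) * voxelSize(stack),
                            voxelSize(stack),
                            config$atlas$n_regions %||% 1L)
      }
    })
    assignment <- stage("regions", assignRegions(det, atlas))
    regions <- regionStats(assignment, atlas)
  }

  mcfg <- config$morphology %||% list()
  morph <- stage("morphology", suppressWarnings(morphologyTable(
    stack, det,
    regions = if (!is.null(atlas)) assignRegions(det, atlas)$region,
    grow_threshold_fraction = mcfg$grow_threshold_fraction %||% 0.5,
    max_radius_um = mcfg$max_radius_um %||% 15)))

  evalRes <- NULL
  if (!is.null(truth) && isTRUE(config$use_truth %||% TRUE)) {
    evalRes <- stage("evaluate", evaluateDetections(
      det, truth,
      max_dist_um = (config$evaluation %||% list())$max_dist_um %||% 5))
  }

  stage("write", {
    writeDetectionsCsv(det, file.path(out_dir, "somas.csv"))
    writeSWC(det, file.path(out_dir, "somas.swc"))
    utils::write.csv(morph, file.path(out_dir, "morph.csv"),
                     row.names = FALSE)
    if (!is.null(regions))
      utils::write.csv(regions, file.path(out_dir, "regions.csv"),
                       row.names = FALSE)
    if (!is.null(truth))
      writeTruthCsv(truth, file.path(out_dir, "truth.csv"))
  })

  report <- list(
    n_detections = nrow(det),
    count_3d = countCells3D(det),
    count_2d_projection = n2d,
    n_morphology_rows = nrow(morph),
    mean_volume_um3 = if (nrow(morph)) mean(morph$volume_um3) else NA,
    regions = regions,
    evaluation = if (!is.null(evalRes))
      evalRes[c("B1", "B2", "B", "recall", "precision")])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  note("done")
  invisible(report)
}
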