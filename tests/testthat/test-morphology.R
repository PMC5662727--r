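test_that("a noise-free sphere is segmented and measured to analytic values", {
  ph <- sphereStack(r = 5, voxel = c(1, 1, 1))
  ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
  sm <- segmentSoma(ph$stack, ctr)
  m <- measureMorphology(sm, ph$stack)
  trueVol <- 4 / 3 * pi * 125
  expect_lt(abs(m$volume_um3 - trueVol) / trueVol, 0.15)
  expect_gte(m$radii_ratio, 1.0)
  expect_lte(m$radii_ratio, 1.2)
  expect_true(m$longest_radius_um >= m$average_radius_um)
  expect_true(m$average_radius_um >= m$shortest_radius_um)

  # exposed-face surface overestimates a smooth sphere, by a bounded factor
  trueArea <- 4 * pi * 25
  expect_gte(m$surface_area_um2, trueArea)
  expect_lte(m$surface_area_um2, 1.7 * trueArea)
})

test_that("ellipsoid semi-axes are recovered within 15 percent", {
  spec <- phantomSpec(shape_um = c(50, 50, 40), voxel_size_um = c(1, 1, 1),
                      n_somas = 1, radius_mean_um = c(8, 5, 4),
                      radius_jitter = 0, neurite_density = 0,
                      noise_sigma = 0, seed = 2)
  ph <- generatePhantom(spec)
  ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
  m <- measureMorphology(segmentSoma(ph$stack, ctr), ph$stack)
  expect_lt(abs(m$longest_radius_um - 8) / 8, 0.15)
  expect_lt(abs(m$shortest_radius_um - 4) / 4, 0.15)
})

test_that("radii ratio is invariant under isotropic scaling", {
  ratioOf <- function(axes, shape) {
    spec <- phantomSpec(shape_um = shape, voxel_size_um = c(1, 1, 1),
                        n_somas = 1, radius_mean_um = axes,
                        radius_jitter = 0, neurite_density = 0,
                        noise_sigma = 0, seed = 3)
    ph <- generatePhantom(spec)
    ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
    measureMorphology(segmentSoma(ph$stack, ctr, max_radius_um = 30),
                      ph$stack)$radii_ratio
  }
  r1 <- ratioOf(c(8, 5, 4), c(50, 50, 40))
  r2 <- ratioOf(c(16, 10, 8), c(90, 90, 70))
  expect_lt(abs(r1 - r2) / r1, 0.10)
})

test_that("morphometry is stable under halving the voxel pitch", {
  measureAt <- function(voxel) {
    ph <- sphereStack(r = 5, voxel = voxel)
    ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
    measureMorphology(segmentSoma(ph$stack, ctr), ph$stack)
  }
  a <- measureAt(c(1, 1, 2))
  b <- measureAt(c(0.5, 0.5, 1))
  expect_lt(abs(a$volume_um3 - b$volume_um3) / b$volume_um3, 0.10)
  expect_lt(abs(a$average_radius_um - b$average_radius_um) /
              b$average_radius_um, 0.10)
})

test_that("region growing respects neighbours and the hard radius", {
  # two somas 12 um apart: each mask excludes the other's centre
  v <- array(10L, dim = c(40, 25, 13))
  dims <- dim(v)
  voxel <- c(1, 1, 2)
  c1 <- c(14, 12, 12); c2 <- c(26, 12, 12)
  v[ballMask(dims, voxel, c1, 4)] <- 200L
  v[ballMask(dims, voxel, c2, 4) & !ballMask(dims, voxel, c1, 4)] <- 200L
  st <- ImageStack3D(v, voxel)
  sm1 <- segmentSoma(st, c1)
  c2vox <- somascope:::.umToVoxel(c2, voxel, c(0, 0, 0))
  lin2 <- c2vox[1] + dims[1] * (c2vox[2] - 1) +
    dims[1] * dims[2] * (c2vox[3] - 1)
  expect_false(lin2 %in% sm1@indices)

  # a small growth ball clips the mask
  ph <- sphereStack(r = 5, voxel = c(1, 1, 1))
  ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
  smSmall <- segmentSoma(ph$stack, ctr, max_radius_um = 3)
  expect_lte(length(smSmall@indices) * 1, 4 / 3 * pi * 27 * 1.2)

  # a dark centre voxel surrounded by bright neighbours (its neighbourhood
  # mean far exceeds it) is flagged as mislocalized
  vv <- array(200L, dim = c(5, 5, 5))
  vv[3, 3, 3] <- 10L
  stDark <- ImageStack3D(vv, c(1, 1, 1))
  expect_error(segmentSoma(stDark, c(2, 2, 2)), "mislocalized")
})

test_that("degenerate and trivial measurement cases behave", {
  st <- ImageStack3D(array(200L, dim = c(5, 5, 5)), c(1, 1, 1))
  one <- new("SomaMask", indices = 63L, dims = c(5L, 5L, 5L),
             voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(measureMorphology(one, st), "degenerate")

  # uniform-intensity soma reports that exact brightness
  ph <- sphereStack(r = 4, voxel = c(1, 1, 1))
  ctr <- as.numeric(truthSomas(ph$truth)[1, c("x_um", "y_um", "z_um")])
  sm <- segmentSoma(ph$stack, ctr, grow_threshold_fraction = 0.98)
  m <- measureMorphology(sm, ph$stack)
  expect_equal(m$mean_brightness, 200)
})

test_that("morphologyTable measures whole detection sets robustly", {
  expect_equal(nrow(morphologyTable(
    ImageStack3D(array(10L, dim = c(5, 5, 5)), c(1, 1, 1)),
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0)))), 0)

  ph <- generatePhantom(quickSpec(shape_um = c(200, 200, 80), n_somas = 20,
                                  seed = 15))
  det <- locateSomas(ph$stack)
  tab <- morphologyTable(ph$stack, det)
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$longest_radius_um >= tab$average_radius_um))
  expect_true(all(tab$average_radius_um >= tab$shortest_radius_um))
  expect_true(all(tab$shortest_radius_um > 0))
  expect_true(all(tab$radii_ratio >= 1))
  expect_equal(tab$radii_ratio,
               tab$longest_radius_um / tab$shortest_radius_um)
  expect_true(all(tab$volume_um3 > 0 & tab$surface_area_um2 > 0))

  # a bad detection is skipped with a warning, not an abort
  det2 <- rbind(det, data.frame(id = 99, x_um = 500, y_um = 2, z_um = 2,
                                radius_um = 4, weight = 1, block = NA))
  expect_warning(tab2 <- morphologyTable(ph$stack, det2), "skipped")
  expect_equal(nrow(tab2), 20)
})

test_that("a region of deliberately larger somas has the largest volumes", {
  big <- generatePhantom(quickSpec(shape_um = c(150, 150, 80), n_somas = 8,
                                   radius_mean_um = c(8, 7, 6),
                                   min_separation_um = 18, seed = 16))
  small <- generatePhantom(quickSpec(shape_um = c(150, 150, 80), n_somas = 8,
                                     radius_mean_um = c(5, 4, 3.5),
                                     seed = 17))
  tb <- morphologyTable(big$stack, locateSomas(big$stack))
  ts <- morphologyTable(small$stack, locateSomas(small$stack))
  expect_gt(mean(tb$volume_um3), mean(ts$volume_um3))
})
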