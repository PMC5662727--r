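test_that("candidate seeding finds distance-transform maxima", {
  # empty mask -> no candidates
  empty <- BinaryMask3D(array(FALSE, dim = c(6, 6, 4)), c(1, 1, 2))
  expect_equal(nrow(seedCandidates(empty)), 0)

  # one ball: exactly 1 candidate within one lateral voxel of the centre,
  # cross-checked against a brute-force EDT argmax oracle
  dims <- c(21, 21, 11)
  voxel <- c(1, 1, 2)
  ctr <- c(10, 10, 10)
  m <- ballMask(dims, voxel, ctr, 5)
  msk <- BinaryMask3D(m, voxel)
  cand <- seedCandidates(msk)
  expect_equal(nrow(cand), 1)
  expect_lte(max(abs(cand[1, ] - ctr)), 1)
  oracle <- edtOracle(m, voxel)
  best <- somascope:::.voxelToUm(
    somascope:::.linToVox(which.max(oracle), dims), voxel, c(0, 0, 0))
  expect_lte(sqrt(sum((cand[1, ] - best)^2)), 2)

  # two balls fused by a thin neck: one candidate per lobe
  m2 <- ballMask(c(25, 15, 11), voxel, c(7, 7, 10), 4) |
        ballMask(c(25, 15, 11), voxel, c(16, 7, 10), 4)
  cand2 <- seedCandidates(BinaryMask3D(m2, voxel))
  expect_gte(nrow(cand2), 2)
})

test_that("the L1 fit recovers isolated and z-aligned somas", {
  # single noise-free sphere: one detection at the centre, plausible radius
  ph <- sphereStack(r = 5, voxel = c(1, 1, 2))
  tr <- truthSomas(ph$truth)
  det <- locateSomas(ph$stack)
  expect_equal(nrow(det), 1)
  expect_lte(max(abs(det[1, c("x_um", "y_um", "z_um")] -
                     tr[1, c("x_um", "y_um", "z_um")])), 1)
  expect_true(det$radius_um[1] %in% c(4, 5, 6))

  # two disjoint r=4 spheres, z-aligned with a 12 um centre gap
  v <- array(10L, dim = c(30, 30, 20))
  st <- ImageStack3D(v, c(1, 1, 2))
  m1 <- ballMask(c(30, 30, 20), c(1, 1, 2), c(15, 15, 13), 4)
  m2 <- ballMask(c(30, 30, 20), c(1, 1, 2), c(15, 15, 25), 4)
  v[m1 | m2] <- 200L
  st <- ImageStack3D(v, c(1, 1, 2))
  det2 <- locateSomas(st)
  expect_equal(nrow(det2), 2)
  expect_equal(sort(round(det2$z_um)), c(13, 25), tolerance = 0.2)

  # empty candidate list -> empty detections
  mask <- extractForeground(st)
  out <- fitL1Model(st, mask,
                    matrix(numeric(0), ncol = 3,
                           dimnames = list(NULL, c("x_um", "y_um", "z_um"))))
  expect_equal(nrow(out), 0)
})

test_that("the proximal-gradient objective never increases", {
  ph <- generatePhantom(quickSpec(n_somas = 8, seed = 12))
  det <- locateSomas(ph$stack)
  objs <- attr(det, "objective")
  expect_gte(length(objs), 2)
  expect_true(all(diff(objs) <= 1e-9 * pmax(1, abs(objs[-length(objs)]))))
})

test_that("the number of detections is non-increasing in lambda", {
  ph <- generatePhantom(quickSpec(n_somas = 8, seed = 13))
  mask <- extractForeground(ph$stack)
  cand <- seedCandidates(mask)
  counts <- vapply(c(0.2, 1, 4, 10, 40, 1e6), function(lam) {
    nrow(fitL1Model(ph$stack, mask, cand, l1Config(lambda = lam)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0) # huge lambda: empty, no error
})

test_that("non-finite intensities are rejected", {
  v <- array(10, dim = c(10, 10, 5))
  v[2, 2, 2] <- NaN
  st <- ImageStack3D(abs(v), c(1, 1, 2))
  msk <- BinaryMask3D(array(TRUE, dim = dim(v)), c(1, 1, 2))
  expect_error(fitL1Model(st, msk, cbind(x_um = 5, y_um = 5, z_um = 4)),
               "non-finite")
})

test_that("block-wise localization equals the whole-volume run", {
  ph <- generatePhantom(quickSpec(shape_um = c(300, 150, 100), n_somas = 30,
                                  seed = 9))
  # single block is the identity
  lay1 <- decomposeBlocks(ph$stack, c(300, 150, 100), halo_um = 0)
  d1 <- locateSomasBlockwise(ph$stack, lay1)
  dW <- locateSomas(ph$stack)
  expect_equal(nrow(d1), nrow(dW))
  expect_equal(sort(d1$x_um), sort(dW$x_um), tolerance = 1e-9)

  # two blocks with adequate halo: 1:1 match within 3 um
  lay2 <- decomposeBlocks(ph$stack, c(150, 150, 100), halo_um = 40)
  d2 <- locateSomasBlockwise(ph$stack, lay2)
  expect_equal(nrow(d2), nrow(dW))
  expect_equal(nrow(matchDetections(d2, dW, max_dist_um = 3)), nrow(dW))
})

test_that("a soma on a block seam is counted exactly once", {
  v <- array(10L, dim = c(40, 20, 10))
  m <- ballMask(c(40, 20, 10), c(1, 1, 2), c(20, 10, 8), 5)
  v[m] <- 200L
  st <- ImageStack3D(v, c(1, 1, 2))
  lay <- decomposeBlocks(st, c(20, 20, 20), halo_um = 15)
  det <- locateSomasBlockwise(st, lay)
  expect_equal(nrow(det), 1)
})

test_that("3D counting is the detection-list length", {
  expect_equal(countCells3D(data.frame()), 0)
  ph <- generatePhantom(quickSpec(shape_um = c(200, 200, 80), n_somas = 20,
                                  seed = 21))
  det <- locateSomas(ph$stack)
  expect_equal(countCells3D(det), 20)
})

test_that("planar z-projection counting merges axially aligned cells", {
  # featureless stack counts zero
  st0 <- ImageStack3D(array(0L, dim = c(20, 20, 10)), c(1, 1, 2))
  expect_equal(countCells2DProjection(st0), 0)
  expect_error(countCells2DProjection(st0, slab_thickness_um = 1),
               "z-step")

  # two disjoint z-aligned spheres in one slab project onto each other
  v <- array(10L, dim = c(40, 40, 20))
  v[ballMask(c(40, 40, 20), c(1, 1, 2), c(20, 20, 12), 4) |
    ballMask(c(40, 40, 20), c(1, 1, 2), c(20, 20, 26), 4)] <- 200L
  st <- ImageStack3D(v, c(1, 1, 2))
  expect_equal(countCells2DProjection(st, slab_thickness_um = 50), 1)
  expect_equal(countCells3D(locateSomas(st)), 2)

  # laterally well-separated somas are counted correctly in projection
  ph <- generatePhantom(quickSpec(shape_um = c(300, 300, 40), n_somas = 12,
                                  min_separation_um = 40,
                                  axial_pair_fraction = 0, seed = 22))
  expect_equal(countCells2DProjection(ph$stack, slab_thickness_um = 50), 12)
})

test_that("localization is deterministic", {
  ph <- generatePhantom(quickSpec(seed = 30))
  a <- locateSomas(ph$stack)
  b <- locateSomas(ph$stack)
  attr(a, "objective") <- NULL
  attr(b, "objective") <- NULL
  expect_identical(a, b)
})
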