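test_that("matching is optimal, thresholded and symmetric", {
  # identical point sets match perfectly
  pts <- cbind(x_um = c(1, 10, 20), y_um = c(1, 5, 9), z_um = c(0, 2, 4))
  m <- matchDetections(pts, pts, max_dist_um = 5)
  expect_equal(nrow(m), 3)
  expect_equal(m$dist_um, rep(0, 3))

  # 3 detections vs 2 truths, one detection far away -> B = 2
  det <- cbind(x_um = c(0, 10, 100), y_um = 0, z_um = 0)
  tru <- cbind(x_um = c(1, 11), y_um = 0, z_um = 0)
  m2 <- matchDetections(det, tru, max_dist_um = 5)
  expect_equal(nrow(m2), 2)
  expect_setequal(m2$detected, c(1, 2))

  # crossed configuration where greedy is suboptimal: compare with an
  # exhaustive enumeration oracle
  det3 <- cbind(x_um = c(0, 3), y_um = 0, z_um = 0)
  tru3 <- cbind(x_um = c(2.5, 7), y_um = 0, z_um = 0)
  m3 <- matchDetections(det3, tru3, max_dist_um = 5)
  oracle <- matchOracle(det3, tru3, 5)
  expect_equal(nrow(m3), oracle$B)
  expect_equal(sum(m3$dist_um), oracle$cost, tolerance = 1e-9)
  greedyCost <- 2.5 + 4 # greedy pairs det1-tru1 then det2-tru2
  expect_lte(sum(m3$dist_um), greedyCost)

  # random small instances against the oracle
  set.seed(1)
  for (rep in 1:5) {
    D <- cbind(x_um = runif(4, 0, 20), y_um = runif(4, 0, 20), z_um = 0)
    Tm <- cbind(x_um = runif(3, 0, 20), y_um = runif(3, 0, 20), z_um = 0)
    got <- matchDetections(D, Tm, max_dist_um = 6)
    want <- matchOracle(D, Tm, 6)
    expect_equal(nrow(got), want$B)
    expect_equal(sum(got$dist_um), want$cost, tolerance = 1e-9)
    # symmetry up to pair orientation
    rev <- matchDetections(Tm, D, max_dist_um = 6)
    expect_equal(sum(rev$dist_um), sum(got$dist_um), tolerance = 1e-9)
  }
})

test_that("recall and precision are exact ratios with guarded edge cases", {
  r <- recallPrecision(57, 59, 57)
  expect_identical(r$recall, 1)
  expect_equal(r$precision, 57 / 59)
  expect_equal(round(r$precision, 4), 0.9661)

  expect_equal(recallPrecision(10, 10, 10)$precision, 1)
  z <- recallPrecision(5, 5, 0)
  expect_equal(z$recall, 0)
  expect_equal(z$precision, 0)

  # scale-free in the counts
  a <- recallPrecision(57, 59, 57)
  b <- recallPrecision(570, 590, 570)
  expect_equal(a$recall, b$recall)
  expect_equal(a$precision, b$precision)

  expect_error(recallPrecision(0, 5, 0), "positive")
  expect_error(recallPrecision(5, 0, 0), "positive")
  expect_error(recallPrecision(5, 5, 6), "inconsistent")
})

test_that("Wilcoxon signed-rank reproduces its closed forms", {
  # five positive distinct differences: W = 0, z = -7.5/sqrt(13.75)
  x <- c(59, 41, 33, 52, 46)
  y <- c(51, 38, 27, 47, 44)
  w <- wilcoxonSignedRank(x, y)
  expect_equal(w$statistic, 0)
  expect_equal(w$z, -7.5 / sqrt(13.75), tolerance = 1e-12)
  expect_equal(round(w$p.value, 3), 0.043)

  # exact enumeration on the same data: 2/32
  we <- wilcoxonSignedRank(x, y, mode = "exact")
  expect_equal(we$p.value, 2 / 32)

  # symmetric pairs: W+ = W-, p ~ 1
  d <- c(3, -3, 5, -5, 7, -7)
  ws <- wilcoxonSignedRank(d)
  expect_equal(ws$Wplus, ws$Wminus)
  expect_equal(ws$p.value, 1)

  expect_error(wilcoxonSignedRank(c(0, 0, 0)), "zero")
})

test_that("exact Wilcoxon equals full sign-pattern enumeration (n <= 8)", {
  set.seed(7)
  for (n in 3:8) {
    for (rep in 1:3) {
      d <- round(rnorm(n, 0, 5))
      d[d == 0] <- 1
      got <- wilcoxonSignedRank(d, mode = "exact")$p.value
      expect_equal(got, wilcoxOracle(d), tolerance = 1e-12)
    }
  }
  # tie-free case agrees with the reference exact distribution
  d <- c(8, -3, 6, 5, -2, 9, 1)
  expect_equal(wilcoxonSignedRank(d, mode = "exact")$p.value,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("normal approximation tracks the exact test for moderate n", {
  # the worst-case two-sided deviation for n in 15..20 sits just under
  # 0.03 (measured by simulation), so that is the asserted envelope
  set.seed(42)
  for (rep in 1:10) {
    d <- sample(c(-1, 1), 16, replace = TRUE) * sample(1:50, 16)
    pe <- wilcoxonSignedRank(d, mode = "exact")$p.value
    pn <- wilcoxonSignedRank(d, mode = "normal_approx")$p.value
    expect_lt(abs(pe - pn), 0.03)
  }
  # and, without ties, matches the uncorrected normal mode of wilcox.test
  d <- c(8, -3, 6, 5, -2, 9, 1, -12, 15, 4, -7, 11, 13, -10, 14)
  expect_equal(wilcoxonSignedRank(d)$p.value,
               stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("one-way ANOVA matches hand-computed results", {
  a <- anovaOneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$F, 1.5, tolerance = 1e-12)
  expect_equal(a$p.value, stats::pf(1.5, 1, 4, lower.tail = FALSE))

  same <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p.value, 1)

  sep <- anovaOneway(list(c(0, 0, 0) + rnorm(3, sd = 1e-3),
                          c(10, 10, 10) + rnorm(3, sd = 1e-3)))
  expect_lt(sep$p.value, 1e-6)

  expect_error(anovaOneway(list(c(1, 2))), "two groups")
  expect_error(anovaOneway(list(1, 2)), "two observations")
  expect_error(anovaOneway(list(c(5, 5), c(5, 5))), "variance")
})

test_that("brightness comparison separates intensities but not replicates", {
  mk <- function(intensity, seed) {
    generatePhantom(quickSpec(shape_um = c(150, 150, 60), n_somas = 12,
                              soma_intensity = intensity, seed = seed))
  }
  # same intensity parameters: H0 should rarely be rejected
  reps <- 10
  pvals <- vapply(seq_len(reps), function(i) {
    a <- mk(200, seed = 100 + i)
    b <- mk(200, seed = 200 + i)
    brightnessCompare(list(a$stack, b$stack),
                      list(truthSomas(a$truth), truthSomas(b$truth)),
                      n_sample = 10, seed = i)$p.overall
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  # a 100 vs 200 intensity difference is unmistakable
  a <- mk(100, seed = 300)
  b <- mk(200, seed = 301)
  res <- brightnessCompare(list(a$stack, b$stack),
                           list(truthSomas(a$truth), truthSomas(b$truth)),
                           n_sample = 10, seed = 1)
  expect_lt(res$p.overall, 0.01)
  expect_equal(res$p.pairwise[1, 2], res$p.overall)

  # sampling everything reproduces the full-population mean
  tr <- truthSomas(b$truth)
  full <- brightnessCompare(list(b$stack, b$stack), list(tr, tr),
                            n_sample = nrow(tr), seed = 1)
  manual <- mean(vapply(seq_len(nrow(tr)), function(i) {
    sm <- segmentSoma(b$stack, tr[i, c("x_um", "y_um", "z_um")])
    mean(voxels(b$stack)[sm@indices])
  }, numeric(1)))
  expect_equal(full$means[1], manual, tolerance = 1e-12)

  expect_error(brightnessCompare(list(a$stack), list(truthSomas(a$truth)),
                                 n_sample = 1000, seed = 1), ">= 1000")
})
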