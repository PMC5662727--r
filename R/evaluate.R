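# Validation statistics: optimal detection-to-truth matching, recall and
# precision, the paired Wilcoxon signed-rank comparison of 3D versus
# planar counts, one-way ANOVA across groups, and brightness comparisons.

#' Optimally match detected centres to ground-truth centres
#'
#' One-to-one assignment minimizing total distance among pairs within
#' `max_dist_um` (Hungarian algorithm on the thresholded distance matrix);
#' each truth and each detection is used at most once. Deterministic and
#' order-independent, unlike greedy matching.
#'
#' @param detected,truth matrices or data.frames of centres with columns
#'   `x_um`, `y_um`, `z_um` (extra columns ignored).
#' @param max_dist_um matching radius in micrometres (> 0); the default of
#'   5 um is about one soma radius.
#' @return data.frame of matched pairs with columns `detected` and `truth`
#'   (row indices into the inputs) and `dist_um`.
#' @export
matchDetections <- function(detected, truth, max_dist_um = 5) {
  stopifnot(max_dist_um > 0)
  asMat <- function(x) {
    if (is.data.frame(x)) x <- as.matrix(x[, c("x_um", "y_um", "z_um")])
    matrix(as.numeric(x), ncol = 3)
  }
  D <- asMat(detected)
  Tm <- asMat(truth)
  empty <- data.frame(detected = integer(0), truth = integer(0),
                      dist_um = numeric(0))
  if (nrow(D) == 0 || nrow(Tm) == 0) return(empty)
  dist2 <- outer(rowSums(D^2), rowSums(Tm^2), "+") - 2 * D %*% t(Tm)
  dist <- sqrt(pmax(dist2, 0))
  BIG <- max_dist_um * 1e6 + 1e6
  cost <- ifelse(dist <= max_dist_um, dist, BIG)
  transposed <- nrow(cost) > ncol(cost)
  if (transposed) cost <- t(cost)
  asg <- cpp_assign(cost)
  rows <- seq_along(asg)
  pairs <- if (transposed) {
    data.frame(detected = asg, truth = rows)
  } else {
    data.frame(detected = rows, truth = asg)
  }
  pairs$dist_um <- dist[cbind(pairs$detected, pairs$truth)]
  pairs <- pairs[pairs$dist_um <= max_dist_um, , drop = FALSE]
  pairs <- pairs[order(pairs$detected), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Recall and precision from manual/automatic/matched counts
#'
#' Recall `R = B/B1` and precision `P = B/B2`, where B1 is the manual (or
#' ground-truth) count, B2 the automatic count and B the number counted by
#' both. Computed as exact ratios.
#'
#' @param B1 manual / true count (> 0).
#' @param B2 automatic count (> 0).
#' @param B matched count, `0 <= B <= min(B1, B2)`.
#' @param match_dist_um optional matching radius recorded in the result.
#' @return list of class `evaluationResult` with elements `B1`, `B2`, `B`,
#'   `recall`, `precision`, `match_dist_um`.
#' @examples
#' recallPrecision(57, 59, 57) # recall 1, precision 57/59
#' @export
recallPrecision <- function(B1, B2, B, match_dist_um = NA_real_) {
  if (B1 < 0 || B2 < 0 || B < 0) stop("counts must be non-negative")
  if (B > min(B1, B2))
    stop("inconsistent counts: B must not exceed min(B1, B2)")
  if (B1 == 0 || B2 == 0)
    stop("recall/precision undefined: B1 and B2 must be positive")
  structure(list(B1 = B1, B2 = B2, B = B,
                 recall = B / B1, precision = B / B2,
                 match_dist_um = match_dist_um),
            class = "evaluationResult")
}

#' @export
print.evaluationResult <- function(x, ...) {
  cat(sprintf("B1 (true) = %g, B2 (detected) = %g, matched B = %g\n",
              x$B1, x$B2, x$B))
  cat(sprintf("recall = %.4f, precision = %.4f (match radius %s um)\n",
              x$recall, x$precision, format(x$match_dist_um)))
  invisible(x)
}

#' Evaluate detections against a ground truth
#'
#' Convenience wrapper: optimal matching at `max_dist_um`, then recall and
#' precision with B1 = true count, B2 = detected count, B = matched count.
#'
#' @inheritParams matchDetections
#' @return An `evaluationResult` (see [recallPrecision()]).
#' @export
evaluateDetections <- function(detected, truth, max_dist_um = 5) {
  if (is(truth, "GroundTruthSet")) truth <- truthSomas(truth)
  pairs <- matchDetections(detected, truth, max_dist_um)
  recallPrecision(B1 = nrow(as.data.frame(truth)),
                  B2 = nrow(as.data.frame(detected)),
                  B = nrow(pairs), match_dist_um = max_dist_um)
}

#' Wilcoxon signed-rank test for paired counts
#'
#' Zero differences are dropped and absolute differences ranked with
#' midranks for ties; the statistic is `W = min(W+, W-)`. In
#' `"normal_approx"` mode (the default, matching legacy statistical
#' packages) the two-sided p-value is `2 * pnorm(z)` with
#' `z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` and no continuity
#' correction. In `"exact"` mode all `2^n` sign patterns are enumerated
#' (n <= 20) and the p-value is the probability of a `min(W+, W-)` at or
#' below the observed one.
#'
#' @param x first members of the pairs, or the differences themselves.
#' @param y optional second members; differences are `x - y`.
#' @param mode `"normal_approx"` or `"exact"`.
#' @return list with `statistic` (W), `Wplus`, `Wminus`, `n` (nonzero
#'   pairs), `z` (normal mode), `p.value`, `mode`.
#' @examples
#' wilcoxonSignedRank(c(59, 41, 33, 52, 46), c(51, 38, 27, 47, 44))$p.value
#' @export
wilcoxonSignedRank <- function(x, y = NULL,
                               mode = c("normal_approx", "exact")) {
  mode <- match.arg(mode)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  Wm <- sum(r[d < 0])
  W <- min(Wp, Wm)
  res <- list(statistic = W, Wplus = Wp, Wminus = Wm, n = n, mode = mode)
  if (mode == "normal_approx") {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (W - mu) / sigma
    res$z <- z
    res$p.value <- min(1, 2 * stats::pnorm(z))
  } else {
    if (n > 20)
      stop("exact enumeration supported for n <= 20 only")
    tot <- sum(r)
    # subset sums over all 2^n sign patterns
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    res$p.value <- mean(pmin(sums, tot - sums) <= W + 1e-9)
  }
  res
}

#' One-way analysis of variance
#'
#' Classical one-way F test across groups, via [stats::aov()].
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `F`, `p.value`, `df` (between, within).
#' @examples
#' anovaOneway(list(c(1, 2, 3), c(2, 3, 4)))$F # 1.5
#' @export
anovaOneway <- function(groups) {
  if (length(groups) < 2)
    stop("at least two groups required")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two observations")
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))) &&
      sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) == 0)
    stop("zero within-group variance in every group: F undefined")
  df <- data.frame(
    y = unlist(groups),
    g = factor(rep(seq_along(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], p.value = s$`Pr(>F)`[1],
       df = c(between = s$Df[1], within = s$Df[2]))
}

#' Compare mean soma brightness across datasets
#'
#' Samples `n_sample` detections per stack (seeded), measures each sampled
#' soma's mean segmented intensity, and tests for group differences with
#' one-way ANOVA overall and for every pair of stacks.
#'
#' @param stacks list of [ImageStack3D-class] objects.
#' @param detections_list list of detection data.frames, one per stack.
#' @param n_sample somas sampled per stack (default 20); each stack must
#'   have at least this many detections.
#' @param seed integer seed for the sampling.
#' @param grow_threshold_fraction,max_radius_um passed to [segmentSoma()].
#' @return list with `means` (per-stack mean brightness), `brightness`
#'   (list of per-soma values), `p.overall`, and `p.pairwise` (matrix).
#' @export
brightnessCompare <- function(stacks, detections_list, n_sample = 20,
                              seed = 1L, grow_threshold_fraction = 0.5,
                              max_radius_um = 15) {
  stopifnot(length(stacks) == length(detections_list))
  k <- length(stacks)
  ns <- vapply(detections_list, nrow, integer(1))
  if (any(ns < n_sample))
    stop(sprintf("every stack needs >= %d detections (got %s)",
                 n_sample, paste(ns, collapse = ", ")))
  bright <- withr::with_seed(seed, lapply(seq_len(k), function(i) {
    det <- detections_list[[i]]
    pick <- if (n_sample < nrow(det))
      sort(sample.int(nrow(det), n_sample)) else seq_len(nrow(det))
    vapply(pick, function(j) {
      sm <- segmentSoma(stacks[[i]], det[j, ], grow_threshold_fraction,
                        max_radius_um)
      mean(stacks[[i]]@voxels[sm@indices])
    }, numeric(1))
  }))
  pw <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1))
    for (j in (i + 1):k) {
      p <- anovaOneway(list(bright[[i]], bright[[j]]))$p.value
      pw[i, j] <- pw[j, i] <- p
    }
  list(means = vapply(bright, mean, numeric(1)),
       brightness = bright,
       p.overall = if (k >= 2) anovaOneway(bright)$p.value else NA_real_,
       p.pairwise = pw)
}
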