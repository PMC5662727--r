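# Shared fixture builders: everything is generated in code at test time.

# Small, quiet phantom spec with overridable fields.
quickSpec <- function(..., seed = 1) {
  args <- list(...)
  defaults <- list(shape_um = c(100, 100, 60), n_somas = 6,
                   neurite_density = 0, seed = seed)
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

# A single noise-free sphere of radius r centred mid-volume.
sphereStack <- function(r = 5, voxel = c(1, 1, 2), pad = 3 * r, seed = 1,
                        noise = 0) {
  spec <- phantomSpec(shape_um = rep(2 * pad, 3), voxel_size_um = voxel,
                      n_somas = 1, radius_mean_um = rep(r, 3),
                      radius_jitter = 0, min_separation_um = 0,
                      axial_pair_fraction = 0, neurite_density = 0,
                      noise_sigma = noise, seed = seed)
  generatePhantom(spec)
}

# Analytic ball mask on the voxel grid (independent of the C++ painter):
# voxel centres within r of the centre (um).
ballMask <- function(dims, voxel, centre, r) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  um <- cbind((g$x - 1) * voxel[1], (g$y - 1) * voxel[2],
              (g$z - 1) * voxel[3])
  d2 <- (um[, 1] - centre[1])^2 + (um[, 2] - centre[2])^2 +
        (um[, 3] - centre[3])^2
  array(d2 <= r^2, dim = dims)
}

# Brute-force 6-connected erosion oracle (one pass).
erodeOracle <- function(m) {
  d <- dim(m)
  out <- m
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!m[x, y, z]) next
    nb <- c(
      if (d[1] > 1) c(if (x > 1) m[x - 1, y, z] else FALSE,
                      if (x < d[1]) m[x + 1, y, z] else FALSE),
      if (d[2] > 1) c(if (y > 1) m[x, y - 1, z] else FALSE,
                      if (y < d[2]) m[x, y + 1, z] else FALSE),
      if (d[3] > 1) c(if (z > 1) m[x, y, z - 1] else FALSE,
                      if (z < d[3]) m[x, y, z + 1] else FALSE))
    if (!all(nb)) out[x, y, z] <- FALSE
  }
  out
}

# Brute-force squared EDT oracle in um (foreground -> nearest background).
edtOracle <- function(m, voxel) {
  d <- dim(m)
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  um <- sweep(g - 1, 2, voxel, "*")
  fg <- which(m)
  bg <- which(!m)
  out <- array(0, dim = d)
  for (i in fg) {
    dd <- colSums((t(um[bg, , drop = FALSE]) - um[i, ])^2)
    out[i] <- min(dd)
  }
  out
}

# Enumerate every one-to-one assignment of detections to truths and return
# the minimum total cost among assignments of maximal cardinality within
# maxDist (small inputs only).
matchOracle <- function(D, Tm, maxDist) {
  nd <- nrow(D)
  nt <- nrow(Tm)
  dist <- sqrt(outer(rowSums(D^2), rowSums(Tm^2), "+") - 2 * D %*% t(Tm))
  best <- list(B = -1, cost = Inf)
  idx <- seq_len(nt)
  k <- min(nd, nt)
  recurse <- function(i, used, B, cost) {
    if (i > nd) {
      if (B > best$B || (B == best$B && cost < best$cost))
        best <<- list(B = B, cost = cost)
      return()
    }
    recurse(i + 1, used, B, cost) # leave detection i unmatched
    for (j in idx[!used]) {
      if (dist[i, j] <= maxDist)
        recurse(i + 1, replace(used, j, TRUE), B + 1, cost + dist[i, j])
    }
  }
  recurse(1, rep(FALSE, nt), 0, 0)
  best
}

# Brute-force exact signed-rank p-value: enumerate every sign pattern.
wilcoxOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  Wobs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wp <- as.numeric(signs %*% r)
  tot <- sum(r)
  mean(pmin(Wp, tot - Wp) <= Wobs + 1e-9)
}
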