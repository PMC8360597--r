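# Fixtures are generated in code; no data files.

# a reproducible random point cloud
random_cloud <- function(n, d = 3, seed = 1, lim = 3) {
  set.seed(seed)
  matrix(runif(n * d, 0, lim), n, d)
}

# a small series of lattice clouds with seeded amplitudes
random_series <- function(n_side = 3, TT = 3, seed = 1, sd = 1, mean = 100) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = seq_len(n_side) - 1,
                             y = seq_len(n_side) - 1, z = 0))
  g <- g[order(g[, 1], g[, 2], g[, 3]), ]  # canonical voxel order
  clouds <- lapply(seq_len(TT) - 1L, function(t)
    time_point_cloud(g, rnorm(nrow(g), mean, sd), t))
  fmri_series(clouds)
}

# canonical multiset key of a diagram for engine-vs-oracle comparison
diagram_key <- function(dim, birth, death, truncated = is.na(death)) {
  sort(paste(dim, signif(birth, 9),
             signif(ifelse(truncated, Inf, death), 9)))
}

engine_key <- function(diag) {
  f <- diag$features
  diagram_key(f$dim, f$birth, f$death, f$truncated)
}

oracle_key <- function(orc) diagram_key(orc$dim, orc$birth, orc$death)

# series of T time points in which a high-amplitude lattice ring drifts
# `step` voxels in +x per time index (noise-free); used for vineyard linking
moving_ring_series <- function(TT = 3, step = 1, nx = 13, ny = 7,
                               ring_radius = 2, contrast = 8) {
  g <- as.matrix(expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1, z = 0))
  ord <- order(g[, 1], g[, 2], g[, 3])
  g <- g[ord, ]
  cy <- (ny - 1) / 2
  clouds <- lapply(seq_len(TT) - 1L, function(t) {
    cx <- ring_radius + 1 + t * step
    rho <- sqrt((g[, 1] - cx)^2 + (g[, 2] - cy)^2)
    amp <- rep(0, nrow(g))
    amp[abs(rho - ring_radius) <= 0.5] <- contrast / 2
    amp[rho < ring_radius - 0.5] <- -contrast / 2
    time_point_cloud(g, amp, t)
  })
  fmri_series(clouds)
}

# two static rings at disjoint centers
two_ring_series <- function(TT = 3, nx = 19, ny = 7, centers = c(3, 15),
                            ring_radius = 2, contrast = 8) {
  g <- as.matrix(expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1, z = 0))
  ord <- order(g[, 1], g[, 2], g[, 3])
  g <- g[ord, ]
  cy <- (ny - 1) / 2
  amp <- rep(0, nrow(g))
  for (cx in centers) {
    rho <- sqrt((g[, 1] - cx)^2 + (g[, 2] - cy)^2)
    amp[abs(rho - ring_radius) <= 0.5] <- contrast / 2
    amp[rho < ring_radius - 0.5] <- -contrast / 2
  }
  fmri_series(lapply(seq_len(TT) - 1L, function(t) time_point_cloud(g, amp, t)))
}
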