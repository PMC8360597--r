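# Deterministic / seeded generators for every geometry and data regime the
# pipeline is validated on.  All generators are pure functions of their
# parameters (and seed); grids are kept small so a full Rips H1 run takes
# seconds.

#' Synthetic geometries
#'
#' @description
#' `bumpy_cube()`: the 27 points of the integer lattice `{0,1,2}^3` --
#' corners, edge midpoints, face midpoints and center of a cube -- with the
#' center displaced by `displacement` units along +z.  At a ball radius where
#' adjacent lattice points' balls intersect but the displaced center is
#' isolated, the union of the remaining 26 balls is a "bumpy" cube surface
#' with a hollow interior: a 2-dimensional homology class.
#'
#' `cylinder_cloud()`: a deterministic lattice on a cylinder surface (a
#' tube), whose first homology is one-dimensional -- every loop is a multiple
#' of the one that winds around the tube.  An optional split removes an
#' angular sector from the top portion of the tube.
#'
#' `ring_volume()`: a lattice grid carrying a ring of uniformly low amplitude
#' around a central cluster of high amplitude, with an intermediate amplitude
#' (a quarter of the way from `low` to `high`) elsewhere.  In hyperspace, at
#' suitable radii, this is two connected components with a non-contractible
#' loop in the low-amplitude one.  The background level is kept close to the
#' ring level so the background merges with the ring early and contributes no
#' competing loop class of its own.
#'
#' @param displacement how far the center point is moved (default 5 units,
#'   several times the lattice spacing so its ball is isolated at the test
#'   radius).
#' @return a [time_point_cloud()] (amplitude 0 for the pure geometries).
#' @examples
#' nrow(bumpy_cube()$coords)  # 27
#' @export
bumpy_cube <- function(displacement = 5) {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  center <- which(g[, 1] == 1 & g[, 2] == 1 & g[, 3] == 1)
  g[center, 3] <- g[center, 3] + displacement
  cl <- time_point_cloud(g, rep(0, nrow(g)), t = 0L)
  canonicalize_cloud(cl)
}

#' @rdname bumpy_cube
#' @param n_angular points around the circumference (>= 8); default 24.
#' @param n_height lattice rows along the axis; default 15.
#' @param radius cylinder radius; default 6.
#' @param spacing vertical spacing between rows; default 1.
#' @param split_sector angular width (radians) of a sector removed from the
#'   top portion of the tube; default 0 (no split).
#' @param split_top fraction of the height (from the top) affected by the
#'   split; default 0.4.
#' @export
cylinder_cloud <- function(n_angular = 24, n_height = 15, radius = 6,
                           spacing = 1, split_sector = 0, split_top = 0.4) {
  if (n_angular < 8) stop("n_angular must be >= 8")
  theta <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  g <- expand.grid(a = theta, h = (seq_len(n_height) - 1L) * spacing)
  keep <- rep(TRUE, nrow(g))
  if (split_sector > 0) {
    top <- g$h > (1 - split_top) * (n_height - 1L) * spacing
    keep <- !(top & g$a < split_sector)
  }
  g <- g[keep, ]
  coords <- cbind(radius * cos(g$a), radius * sin(g$a), g$h)
  canonicalize_cloud(time_point_cloud(coords, rep(0, nrow(coords)), t = 0L))
}

#' @rdname bumpy_cube
#' @param grid lattice dimensions `c(nx, ny, nz)`; default `c(9, 9, 3)`.
#' @param ring_radius in-plane radius of the low-amplitude ring around the
#'   grid center; default 3.
#' @param low amplitude on the ring; default 0.
#' @param high amplitude on the central cluster (> `low`).
#' @export
ring_volume <- function(grid = c(9, 9, 3), ring_radius = 3, low = 0,
                        high = 10) {
  if (high < low) stop("high must be >= low (equal gives a flat lattice)")
  g <- as.matrix(expand.grid(x = seq_len(grid[1]) - 1L,
                             y = seq_len(grid[2]) - 1L,
                             z = seq_len(grid[3]) - 1L))
  cx <- (grid[1] - 1) / 2; cy <- (grid[2] - 1) / 2
  rho <- sqrt((g[, 1] - cx)^2 + (g[, 2] - cy)^2)
  amp <- rep(low + (high - low) / 4, nrow(g))
  amp[rho < ring_radius - 0.5] <- high
  amp[abs(rho - ring_radius) <= 0.5] <- low
  canonicalize_cloud(time_point_cloud(g, amp, t = 0L))
}

#' Block design of the associative-learning task
#'
#' Contiguous blocks of `trs_per_block` time indices cycling through the
#' given conditions, repeated `n_cycles` times.  The defaults reproduce the
#' acquisition structure of a blocked associative-learning run: 4 conditions
#' x 9 TRs (27 s at TR = 3 s) x 8 cycles = 288 time indices.
#'
#' @param trs_per_block time indices per block; default 9.
#' @param cycle condition sequence of one cycle; default encoding,
#'   consolidation, retrieval, consolidation.
#' @param n_cycles number of cycles; default 8.
#' @return a [task_design()].
#' @examples
#' length(make_design()$labels)  # 288
#' @export
make_design <- function(trs_per_block = 9,
                        cycle = c("encoding", "consolidation",
                                  "retrieval", "consolidation"),
                        n_cycles = 8) {
  stopifnot(trs_per_block >= 1, n_cycles >= 1, length(cycle) >= 1)
  task_design(rep(rep(cycle, each = trs_per_block), n_cycles))
}

#' Seeded task series with an embedded condition-modulated loop
#'
#' A lattice grid whose amplitudes are baseline plus seeded Gaussian noise,
#' carrying -- centered in `loop_region` -- a ring of elevated amplitude
#' around a depressed core.  The ring-minus-core contrast is `contrast_on`
#' at time indices of `on_condition` and `contrast_off` otherwise, so with
#' `contrast_on > contrast_off` the hyperspace cloud carries a loop class in
#' the region exactly when the task is in the on condition.
#'
#' The defaults are the package's reference simulation conditions: a
#' 7 x 7 x 1 grid (49 voxels, the scale of a small ROI slab), ring radius 2
#' lattice units, contrast 8 against noise with sd 0.5 (a strong, clearly
#' supra-threshold effect), no modulation outside encoding.
#'
#' @param design a [task_design()]; default [make_design()].
#' @param grid lattice dimensions; default `c(7, 7, 1)`.
#' @param ring_radius in-plane ring radius; default 2.
#' @param baseline baseline amplitude; default 0.
#' @param contrast_on,contrast_off ring-minus-core contrast during / outside
#'   the on condition; defaults 8 and 0.
#' @param noise_sd sd of iid Gaussian voxel noise; default 0.5.
#' @param on_condition condition during which the loop contrast is
#'   `contrast_on`; default `"encoding"`.
#' @param ar first-order autoregressive coefficient of the temporal noise
#'   (0 = white, the default; used for permutation-calibration checks).
#' @param seed RNG seed; identical seeds give identical series.
#' @return a list: `series` (an [fmri_series()]), `design`, and
#'   `ground_truth` with the loop region (a [mask_box()]), the ring center,
#'   and the on-condition time positions.
#' @export
task_series <- function(design = make_design(), grid = c(7, 7, 1),
                        ring_radius = 2, baseline = 0, contrast_on = 8,
                        contrast_off = 0, noise_sd = 0.5,
                        on_condition = "encoding", ar = 0, seed = 1) {
  stopifnot(inherits(design, "task_design"))
  if (contrast_on < contrast_off || contrast_off < 0)
    stop("need contrast_on >= contrast_off >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  TT <- length(design$labels)
  g <- as.matrix(expand.grid(x = seq_len(grid[1]) - 1L,
                             y = seq_len(grid[2]) - 1L,
                             z = seq_len(grid[3]) - 1L))
  ord <- order(g[, 1], g[, 2], g[, 3])
  g <- g[ord, , drop = FALSE]
  n <- nrow(g)
  cx <- (grid[1] - 1) / 2; cy <- (grid[2] - 1) / 2
  rho <- sqrt((g[, 1] - cx)^2 + (g[, 2] - cy)^2)
  ring <- abs(rho - ring_radius) <= 0.5
  core <- rho < ring_radius - 0.5

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n * TT, sd = noise_sd), n, TT)
  if (ar != 0 && TT > 1) {
    for (k in 2:TT)
      noise[, k] <- ar * noise[, k - 1] + sqrt(1 - ar^2) * noise[, k]
  }
  amp <- matrix(baseline, n, TT) + noise
  on_idx <- which(design$labels == on_condition)
  for (k in seq_len(TT)) {
    contrast <- if (k %in% on_idx) contrast_on else contrast_off
    amp[ring, k] <- amp[ring, k] + contrast / 2
    amp[core, k] <- amp[core, k] - contrast / 2
  }
  series <- structure(list(coords = structure(g, dimnames = list(NULL, c("x", "y", "z"))),
                           amplitudes = amp, t = seq_len(TT) - 1L),
                      class = "fmri_series")
  pad <- 1
  region <- mask_box(c(cx - ring_radius - pad, cx + ring_radius + pad),
                     c(cy - ring_radius - pad, cy + ring_radius + pad),
                     range(g[, 3]))
  list(series = series, design = design,
       ground_truth = list(region = region, center = c(cx, cy),
                           on_positions = on_idx,
                           on_condition = on_condition))
}
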