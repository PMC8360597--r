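# Per-timepoint Vietoris-Rips persistent homology of the 4-D hyperspace
# cloud, truncated at a maximum radius, with representative cycles.
#
# Radius convention: a simplex enters the filtration at HALF its diameter
# (balls of radius r around two points touch when r is half their distance),
# so on a unit lattice the square loop classes are born at exactly 0.5.
# Coefficients are GF(2).  Classes still alive at r_max are reported as
# truncated (death = NA) and never assigned a fake death; raising r_max only
# completes the diagram, it never changes existing finite pairs.

#' Embed a voxel cloud in stereotactic hyperspace
#'
#' One 4-D point per voxel: the three stereotactic coordinates plus the
#' (normalized) amplitude as a fourth Euclidean dimension, order preserved.
#'
#' @param cloud a [time_point_cloud()], normally after
#'   [normalize_amplitudes()].
#' @return an n x 4 numeric matrix with columns x, y, z, w.
#' @export
embed_hyperspace <- function(cloud) {
  stopifnot(inherits(cloud, "time_point_cloud"))
  out <- cbind(cloud$coords, w = cloud$amplitude)
  colnames(out) <- c("x", "y", "z", "w")
  out
}

#' Build a truncated Vietoris-Rips filtration
#'
#' Enumerates all simplices of dimension `<= max_dim + 1` whose filtration
#' radius (half the maximum pairwise distance among vertices) is `<= r_max`,
#' in the deterministic total order (radius, dimension, lexicographic vertex
#' tuple).  Tie-breaking by vertex tuple makes the downstream reduction -- and
#' hence representative cycles -- reproducible on tie-heavy lattice data.
#'
#' @param points numeric matrix of point coordinates (any dimension; rows are
#'   points).  Typically the output of [embed_hyperspace()].
#' @param r_max maximum filtration radius; default 12.
#' @param max_dim maximum homology dimension, 1 (loops) or 2 (voids);
#'   default 1.  Dimension 2 enumerates 3-simplices and is combinatorially
#'   explosive, hence the tighter point cap.
#' @param point_cap refuse clouds larger than this (default 2500 points for
#'   `max_dim = 1`, 400 for `max_dim = 2`); a guard against runaway simplex
#'   enumeration.  Use a tighter mask or a smaller `r_max` instead of raising
#'   it casually.
#' @return an object of class `rips_filtration`.
#' @export
build_rips <- function(points, r_max = 12, max_dim = 1,
                       point_cap = if (max_dim >= 2) 400L else 2500L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("need at least one point")
  if (!is.numeric(r_max) || r_max <= 0) stop("r_max must be positive")
  if (!max_dim %in% c(1L, 2L)) stop("max_dim must be 1 or 2")
  if (nrow(points) > point_cap)
    stop("point cloud has ", nrow(points), " points, above the cap of ",
         point_cap, " for max_dim = ", max_dim,
         "; apply a tighter mask or lower r_max")
  simplices <- cpp_rips_filtration(points, r_max, as.integer(max_dim))
  structure(list(simplices = simplices, points = points,
                 n_points = nrow(points), r_max = r_max,
                 max_dim = as.integer(max_dim)),
            class = "rips_filtration")
}

#' @export
print.rips_filtration <- function(x, ...) {
  counts <- vapply(x$simplices, function(s) nrow(s$vertices), integer(1))
  cat(sprintf("<rips_filtration> %d points, r_max = %g, simplices by dim: %s\n",
              x$n_points, x$r_max,
              paste(seq_along(counts) - 1L, counts, sep = ":", collapse = " ")))
  invisible(x)
}

#' Persistence of a Rips filtration
#'
#' Column reduction of the boundary matrix over GF(2), columns processed in
#' filtration order.  Zero-persistence pairs (birth = death) are discarded;
#' classes unpaired at `r_max` are reported as truncated.  Every reported
#' class carries a representative: for a finite class of dimension 1 or 2,
#' the cycle stored in the reduced column that kills it; for a truncated
#' class, a cycle read off the accumulated column operations; for dimension
#' 0, the vertex whose component is born.
#'
#' @param filtration a [build_rips()] result.
#' @param t time index to record on the diagram (default `NA`).
#' @return an object of class `persistence_diagram`: a feature table
#'   (`feature_id`, `dim`, `birth`, `death`, `persistence`, `truncated`)
#'   sorted by (dim, birth, death), plus aligned representative cycles.
#'   Truncated features have `death = NA` and
#'   `persistence = r_max - birth`.
#' @export
compute_persistence <- function(filtration, t = NA_integer_) {
  stopifnot(inherits(filtration, "rips_filtration"))
  res <- cpp_persistence(filtration$simplices, filtration$n_points,
                         filtration$r_max, filtration$max_dim)
  truncated <- is.na(res$death)
  persistence <- ifelse(truncated, filtration$r_max - res$birth,
                        res$death - res$birth)
  nf <- length(res$dim)
  features <- data.frame(
    feature_id = seq_len(nf),
    dim = res$dim,
    birth = res$birth,
    death = res$death,
    persistence = persistence,
    truncated = truncated
  )
  new_persistence_diagram(features, res$representatives,
                          filtration$points, t, filtration$r_max,
                          filtration$max_dim)
}

new_persistence_diagram <- function(features, representatives, points, t,
                                    r_max, max_dim) {
  structure(list(features = features, representatives = representatives,
                 points = points, t = as.integer(t), r_max = r_max,
                 max_dim = max_dim),
            class = "persistence_diagram")
}

#' One-call Rips persistence of a point cloud
#'
#' Convenience wrapper: [build_rips()] followed by [compute_persistence()].
#'
#' @inheritParams build_rips
#' @inheritParams compute_persistence
#' @return a `persistence_diagram`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' rips_persistence(sq, r_max = 2)  # one H1 class at (0.5, sqrt(2) / 2)
#' @export
rips_persistence <- function(points, r_max = 12, max_dim = 1,
                             t = NA_integer_,
                             point_cap = if (max_dim >= 2) 400L else 2500L) {
  compute_persistence(build_rips(points, r_max, max_dim, point_cap), t = t)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  f <- x$features
  cat(sprintf("<persistence_diagram> t = %s, r_max = %g, %d features\n",
              ifelse(is.na(x$t), "?", x$t), x$r_max, nrow(f)))
  for (d in sort(unique(f$dim))) {
    fd <- f[f$dim == d, ]
    cat(sprintf("  H%d: %d classes (%d truncated), max persistence %.4g\n",
                d, nrow(fd), sum(fd$truncated),
                if (nrow(fd)) max(fd$persistence) else 0))
  }
  invisible(x)
}

#' @export
as.data.frame.persistence_diagram <- function(x, ...) x$features

#' @export
plot.persistence_diagram <- function(x, dims = NULL, ...) {
  f <- x$features
  if (!is.null(dims)) f <- f[f$dim %in% dims, ]
  lim <- c(0, x$r_max)
  death <- ifelse(f$truncated, x$r_max, f$death)
  plot(f$birth, death, xlim = lim, ylim = lim,
       pch = ifelse(f$truncated, 2L, 16L), col = f$dim + 1L,
       xlab = "birth radius", ylab = "death radius", ...)
  abline(0, 1, col = "grey")
  legend("bottomright", legend = paste0("H", sort(unique(f$dim))),
         col = sort(unique(f$dim)) + 1L, pch = 16L, bty = "n")
  invisible(x)
}

#' Representative cycle of a feature
#'
#' @param diagram a `persistence_diagram`.
#' @param feature_id the feature's id in the diagram's feature table.
#' @param what `"vertices"` for the unique 3-D voxel coordinates of the
#'   cycle's vertex set, `"simplices"` for the cycle's simplex list (vertex
#'   index matrix, one simplex per row), `"indices"` for the unique vertex
#'   indices.
#' @return matrix or integer vector as requested.
#' @export
representative <- function(diagram, feature_id,
                           what = c("vertices", "simplices", "indices")) {
  what <- match.arg(what)
  stopifnot(inherits(diagram, "persistence_diagram"))
  i <- match(feature_id, diagram$features$feature_id)
  if (is.na(i)) stop("no feature with id ", feature_id)
  simp <- diagram$representatives[[i]]
  if (what == "simplices") return(simp)
  idx <- sort(unique(as.integer(simp)))
  if (what == "indices") return(idx)
  diagram$points[idx, 1:3, drop = FALSE]
}

representative_centroid <- function(diagram, feature_id) {
  colMeans(representative(diagram, feature_id, "vertices"))
}

#' Persistence diagrams at every time index
#'
#' Embeds each time point of a (normalized) series in hyperspace and computes
#' its truncated Rips persistence; features below `persistence_floor` are
#' omitted.  Deterministic given the series.
#'
#' @param series a normalized [fmri_series()].
#' @param r_max maximum filtration radius (default 12).
#' @param max_dim maximum homology dimension (default 1).
#' @param persistence_floor drop features with persistence below this
#'   (default 0, keep all).
#' @param point_cap see [build_rips()].
#' @return a list of `persistence_diagram`s (class `diagram_stack`), one per
#'   time index.
#' @export
diagrams_over_time <- function(series, r_max = 12, max_dim = 1,
                               persistence_floor = 0,
                               point_cap = if (max_dim >= 2) 400L else 2500L) {
  stopifnot(inherits(series, "fmri_series"))
  out <- lapply(seq_along(series$t), function(i) {
    cl <- get_cloud(series, i)
    dg <- rips_persistence(embed_hyperspace(cl), r_max = r_max,
                           max_dim = max_dim, t = cl$t,
                           point_cap = point_cap)
    filter_diagram(dg, persistence_floor)
  })
  structure(out, class = "diagram_stack")
}

filter_diagram <- function(diagram, persistence_floor) {
  if (persistence_floor <= 0) return(diagram)
  keep <- diagram$features$persistence >= persistence_floor
  diagram$features <- diagram$features[keep, , drop = FALSE]
  diagram$representatives <- diagram$representatives[keep]
  rownames(diagram$features) <- NULL
  diagram
}

#' @export
print.diagram_stack <- function(x, ...) {
  nf <- vapply(x, function(d) nrow(d$features), integer(1))
  cat(sprintf("<diagram_stack> %d time indices, %d features total\n",
              length(x), sum(nf)))
  invisible(x)
}

#' Export a diagram stack as a flat feature table
#'
#' Columns `t, dim, birth, death, persistence, truncated, feature_id`;
#' representatives are exported separately by [write_representatives()].
#'
#' @param diagrams a `diagram_stack` (or list of diagrams).
#' @param path optional file to write as CSV.
#' @return the combined data frame (invisibly if `path` given).
#' @export
write_diagrams <- function(diagrams, path = NULL) {
  tabs <- lapply(diagrams, function(d)
    cbind(t = d$t, d$features[, c("dim", "birth", "death", "persistence",
                                  "truncated", "feature_id")]))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @rdname write_diagrams
#' @export
write_representatives <- function(diagrams, path = NULL) {
  rows <- list()
  for (d in diagrams) {
    for (id in d$features$feature_id) {
      v <- representative(d, id, "vertices")
      rows[[length(rows) + 1L]] <-
        data.frame(t = d$t, feature_id = id,
                   x = v[, 1], y = v[, 2], z = v[, 3])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(), feature_id = integer(),
               x = numeric(), y = numeric(), z = numeric())
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Brute-force persistence oracle
#'
#' Recomputes the persistence multiset of small clouds (about 14 points or
#' fewer) by an algorithm independent of the reduction engine: homology ranks
#' at every critical radius via rank-nullity over GF(2), with interval
#' multiplicities recovered by inclusion-exclusion.  Intended for validation;
#' cost grows combinatorially with the point count.
#'
#' @inheritParams build_rips
#' @return data frame with columns `dim`, `birth`, `death` (`NA` = truncated
#'   at `r_max`), positive-persistence classes only.
#' @export
rips_persistence_bruteforce <- function(points, r_max = 12, max_dim = 1) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) > 16L) stop("oracle is limited to small clouds (<= 16 points)")
  res <- cpp_oracle_persistence(points, r_max, as.integer(max_dim))
  out <- data.frame(dim = res$dim, birth = res$birth, death = res$death)
  out[order(out$dim, out$birth, ifelse(is.na(out$death), Inf, out$death)), ,
      drop = FALSE]
}
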