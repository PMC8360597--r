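# Vineyards: per-timepoint diagrams stacked over time, with edges between
# loop features at consecutive time indices shaded by the 3-D Hausdorff
# distance between their representative cycles, and vine selection.
#
# Only dimension-1 features participate in linking (the pipeline tracks
# loops); dimensions 0/2 are still exported in the diagrams.  Edge shade is
# the linear clamp 1 - d / d_ref: the simplest monotone darkness rule, which
# makes shade 0 an exact prunability criterion.

#' Hausdorff distance between finite point sets in stereotactic space
#'
#' `max(max_a min_b |a - b|, max_b min_a |a - b|)` with Euclidean distances,
#' computed on the first three (spatial) columns only -- the amplitude
#' dimension is deliberately excluded, so proximity means anatomical
#' proximity.
#'
#' @param A,B numeric matrices of points (rows), at least 3 columns.
#' @return the Hausdorff distance, a nonnegative number.
#' @examples
#' hausdorff3(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))  # 5
#' @export
hausdorff3 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) < 1L || nrow(B) < 1L) stop("point sets must be non-empty")
  A <- A[, 1:3, drop = FALSE]; B <- B[, 1:3, drop = FALSE]
  cross <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2 +
    outer(A[, 3], B[, 3], "-")^2
  row_min <- cross[cbind(seq_len(nrow(cross)),
                         max.col(-cross, ties.method = "first"))]
  col_min <- cross[cbind(max.col(-t(cross), ties.method = "first"),
                         seq_len(ncol(cross)))]
  sqrt(max(row_min, col_min))
}

#' Assemble a vineyard from a stack of diagrams
#'
#' For every ordered pair of dimension-1 features at consecutive time
#' indices, one edge records the 3-D Hausdorff distance between their
#' representative loops and the shade `clamp(1 - distance / d_ref, 0, 1)`
#' (1 = darkest / spatially closest).
#'
#' @param diagrams a [diagrams_over_time()] result (or list of
#'   `persistence_diagram`s ordered by time).
#' @param d_ref reference distance at which shade reaches 0; default 4
#'   stereotactic units.
#' @param prune drop edges with shade 0 from storage? Default `FALSE`
#'   (pruning is a storage optimization only).
#' @return an object of class `vineyard`: the diagrams plus an edge table
#'   `(t_from, from_id, to_id, distance, shade)`.
#' @export
build_vineyard <- function(diagrams, d_ref = 4, prune = FALSE) {
  stopifnot(length(diagrams) >= 1L, d_ref > 0)
  # cache loop ids and representative vertex coordinates per diagram
  loops <- lapply(diagrams, function(d) {
    ids <- d$features$feature_id[d$features$dim == 1L]
    list(ids = ids,
         reps = lapply(ids, function(id) representative(d, id, "vertices")))
  })
  t_from <- from_id <- to_id <- integer(0)
  distance <- numeric(0)
  for (i in seq_len(length(diagrams) - 1L)) {
    l1 <- loops[[i]]; l2 <- loops[[i + 1L]]
    n1 <- length(l1$ids); n2 <- length(l2$ids)
    if (!n1 || !n2) next
    dm <- matrix(0, n1, n2)
    for (a in seq_len(n1))
      for (b in seq_len(n2))
        dm[a, b] <- hausdorff3(l1$reps[[a]], l2$reps[[b]])
    t_from <- c(t_from, rep(diagrams[[i]]$t, n1 * n2))
    from_id <- c(from_id, rep(l1$ids, times = n2))
    to_id <- c(to_id, rep(l2$ids, each = n1))
    distance <- c(distance, as.vector(dm))
  }
  edges <- data.frame(t_from = t_from, from_id = from_id, to_id = to_id,
                      distance = distance,
                      shade = pmin(pmax(1 - distance / d_ref, 0), 1))
  ord <- order(edges$t_from, edges$from_id, edges$to_id)
  edges <- edges[ord, , drop = FALSE]
  if (prune) edges <- edges[edges$shade > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(diagrams = diagrams, edges = edges, d_ref = d_ref),
            class = "vineyard")
}

#' @export
print.vineyard <- function(x, ...) {
  cat(sprintf("<vineyard> %d time indices, %d edges (d_ref = %g)\n",
              length(x$diagrams), nrow(x$edges), x$d_ref))
  invisible(x)
}

#' @export
plot.vineyard <- function(x, ...) {
  ts <- vapply(x$diagrams, function(d) d$t, integer(1))
  plot(NA, xlim = range(ts), ylim = c(0, max(vapply(x$diagrams,
       function(d) d$r_max, numeric(1)))),
       xlab = "time index", ylab = "persistence (H1)", ...)
  pers <- function(d, id) d$features$persistence[match(id, d$features$feature_id)]
  for (e in seq_len(nrow(x$edges))) {
    i <- match(x$edges$t_from[e], ts)
    graphics::segments(ts[i], pers(x$diagrams[[i]], x$edges$from_id[e]),
                       ts[i + 1L], pers(x$diagrams[[i + 1L]], x$edges$to_id[e]),
                       col = grey(1 - x$edges$shade[e]))
  }
  for (i in seq_along(ts)) {
    f <- x$diagrams[[i]]$features
    f <- f[f$dim == 1L, ]
    if (nrow(f)) graphics::points(rep(ts[i], nrow(f)), f$persistence, pch = 16)
  }
  invisible(x)
}

#' Strip a vineyard to a spatially constrained vine
#'
#' Retains, per time index, the dimension-1 features with persistence at
#' least `min_persistence` (truncated features count `r_max - birth`) whose
#' representative centroid lies inside `region`.  Time indices with no
#' retained feature yield empty diagrams -- intermittent vines are legal and
#' meaningful, since absence itself is signal for the downstream test.
#'
#' @param vineyard a [build_vineyard()] result.
#' @param region a [mask_box()] (or [mask_voxels()]) in stereotactic space.
#' @param min_persistence persistence floor, default 0.8.
#' @param centroid use the representative's centroid for region membership
#'   (default, robust to single stray vertices); `FALSE` demands all cycle
#'   vertices inside the region.
#' @return an object of class `vine_selection`: per-timepoint stripped
#'   diagrams plus the selection parameters.
#' @export
extract_vine <- function(vineyard, region, min_persistence = 0.8,
                         centroid = TRUE) {
  stopifnot(inherits(vineyard, "vineyard"), inherits(region, "mask_region"))
  stripped <- lapply(vineyard$diagrams, function(d) {
    f <- d$features
    keep <- f$dim == 1L & f$persistence >= min_persistence
    for (i in which(keep)) {
      v <- representative(d, f$feature_id[i], "vertices")
      inside <- mask_membership(region, v)
      keep[i] <- if (centroid)
        mask_membership(region, matrix(colMeans(v), 1L)) else all(inside)
    }
    d$features <- f[keep, , drop = FALSE]
    d$representatives <- d$representatives[keep]
    rownames(d$features) <- NULL
    d
  })
  structure(list(diagrams = stripped, region = region,
                 min_persistence = min_persistence,
                 t = vapply(stripped, function(d) d$t, integer(1))),
            class = "vine_selection")
}

#' @export
print.vine_selection <- function(x, ...) {
  n <- vapply(x$diagrams, function(d) nrow(d$features), integer(1))
  cat(sprintf(
    "<vine_selection> %d/%d time indices occupied, floor %g, %d features\n",
    sum(n > 0), length(n), x$min_persistence, sum(n)))
  invisible(x)
}

#' Rank candidate vine regions
#'
#' The published workflow selects its region by eye; this is a deterministic,
#' auditable surrogate.  Dimension-1 features are chained greedily across
#' consecutive time indices through edges with Hausdorff distance at most
#' `d_link`; each chain is scored by (total persistence) x (chain length) and
#' reported with the bounding box of its representatives, padded by
#' `d_link / 2`.
#'
#' @param vineyard a [build_vineyard()] result (>= 2 time indices).
#' @param d_link maximum representative distance for chaining; default
#'   `d_ref / 2`.
#' @param persistence_floor ignore features below this persistence
#'   (default 0).
#' @return a data frame of candidate regions ordered by decreasing score,
#'   with columns `score`, `length`, `total_persistence`, `t_start`, `t_end`
#'   and padded box limits; class `vine_candidates`.
#' @export
rank_vines <- function(vineyard, d_link = vineyard$d_ref / 2,
                       persistence_floor = 0) {
  stopifnot(inherits(vineyard, "vineyard"), length(vineyard$diagrams) >= 2L)
  dgs <- vineyard$diagrams
  ts <- vapply(dgs, function(d) d$t, integer(1))
  feats <- list()  # (i = position, id, persistence)
  for (i in seq_along(dgs)) {
    f <- dgs[[i]]$features
    f <- f[f$dim == 1L & f$persistence >= persistence_floor, , drop = FALSE]
    for (k in seq_len(nrow(f)))
      feats[[length(feats) + 1L]] <- list(i = i, id = f$feature_id[k],
                                          pers = f$persistence[k])
  }
  if (!length(feats))
    return(structure(data.frame(), class = c("vine_candidates", "data.frame")))
  used <- character(0)
  keyf <- function(fe) paste(fe$i, fe$id)
  ord <- order(-vapply(feats, function(fe) fe$pers, numeric(1)))
  reps <- function(fe) representative(dgs[[fe$i]], fe$id, "vertices")
  neighbors <- function(fe, dir) {
    j <- fe$i + dir
    if (j < 1L || j > length(dgs)) return(NULL)
    f <- dgs[[j]]$features
    f <- f[f$dim == 1L & f$persistence >= persistence_floor, , drop = FALSE]
    best <- NULL; bestd <- Inf
    for (k in seq_len(nrow(f))) {
      cand <- list(i = j, id = f$feature_id[k], pers = f$persistence[k])
      if (keyf(cand) %in% used) next
      d <- hausdorff3(reps(fe), reps(cand))
      if (d <= d_link && d < bestd) { best <- cand; bestd <- d }
    }
    best
  }
  chains <- list()
  for (o in ord) {
    fe <- feats[[o]]
    if (keyf(fe) %in% used) next
    chain <- list(fe); used <- c(used, keyf(fe))
    for (dir in c(1L, -1L)) {
      cur <- fe
      repeat {
        nxt <- neighbors(cur, dir)
        if (is.null(nxt)) break
        used <- c(used, keyf(nxt))
        chain[[length(chain) + 1L]] <- nxt
        cur <- nxt
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }
  rows <- lapply(chains, function(chain) {
    pts <- do.call(rbind, lapply(chain, reps))
    tp <- sum(vapply(chain, function(fe) fe$pers, numeric(1)))
    is <- vapply(chain, function(fe) fe$i, integer(1))
    pad <- d_link / 2
    data.frame(score = tp * length(chain), length = length(chain),
               total_persistence = tp,
               t_start = min(ts[is]), t_end = max(ts[is]),
               xmin = min(pts[, 1]) - pad, xmax = max(pts[, 1]) + pad,
               ymin = min(pts[, 2]) - pad, ymax = max(pts[, 2]) + pad,
               zmin = min(pts[, 3]) - pad, zmax = max(pts[, 3]) + pad)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("vine_candidates", "data.frame"))
}

#' Bounding-box mask of a ranked vine candidate
#'
#' @param candidates a [rank_vines()] result.
#' @param rank which candidate (default 1, the top score).
#' @return a [mask_box()] covering the candidate's padded bounding box.
#' @export
candidate_region <- function(candidates, rank = 1L) {
  stopifnot(nrow(candidates) >= rank)
  r <- candidates[rank, ]
  mask_box(c(r$xmin, r$xmax), c(r$ymin, r$ymax), c(r$zmin, r$zmax))
}

#' Export a vineyard as structured JSON
#'
#' Diagrams (flat feature table), edges, `d_ref`, and per-feature
#' representative loops, for external plotting.
#'
#' @param vineyard a [build_vineyard()] result.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_vineyard_json <- function(vineyard, path) {
  obj <- list(
    format = "fmrivine-vineyard-1",
    d_ref = vineyard$d_ref,
    diagrams = write_diagrams(vineyard$diagrams),
    representatives = write_representatives(vineyard$diagrams),
    edges = vineyard$edges
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
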