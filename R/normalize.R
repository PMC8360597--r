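# Parameterless linear normalization of the amplitude dimension.
#
# The amplitude is rescaled by the unique increasing linear map that sends the
# series-wide amplitude minimum to a0 and the maximum to a1, where a0 (a1) is
# the average of the per-axis coordinate minima (maxima).  After the map, the
# amplitude range equals the average of the three spatial coordinate ranges,
# making the fourth hyperspace dimension commensurate with the spatial three.
# The map is characterized by those two endpoint properties; it has no free
# parameters, and it makes downstream persistence computations equivariant
# under a change of spatial units (all radii scale with the unit).

#' Normalization bounds of a series
#'
#' @param series an [fmri_series()].
#' @return an object of class `norm_bounds` with fields `a0` (mean of the
#'   per-axis coordinate minima), `a1` (mean of the per-axis maxima), and
#'   `f_min`, `f_max` (raw amplitude extremes over all voxels and all time
#'   indices).
#' @examples
#' s <- fmri_series(list(time_point_cloud(expand.grid(0:2, 0:2, 0:2), 1:27, 0)))
#' compute_bounds(s)  # a0 = 0, a1 = 2, f over [1, 27]
#' @export
compute_bounds <- function(series) {
  stopifnot(inherits(series, "fmri_series"))
  structure(list(a0 = mean(apply(series$coords, 2L, min)),
                 a1 = mean(apply(series$coords, 2L, max)),
                 f_min = min(series$amplitudes),
                 f_max = max(series$amplitudes)),
            class = "norm_bounds")
}

#' @export
print.norm_bounds <- function(x, ...) {
  cat(sprintf("<norm_bounds> a0 = %g, a1 = %g, f in [%g, %g]\n",
              x$a0, x$a1, x$f_min, x$f_max))
  invisible(x)
}

#' Normalize amplitudes into spatial units
#'
#' Applies the unique increasing linear map sending `f_min -> a0` and
#' `f_max -> a1`; spatial coordinates are untouched.  A constant-amplitude
#' series (f_min = f_max) maps to the midpoint `(a0 + a1) / 2`, the symmetric
#' limit of the linear map.
#'
#' @param series an [fmri_series()].
#' @param bounds a [compute_bounds()] result; defaults to the bounds of
#'   `series` itself.  Supplying bounds from a different series whose
#'   amplitudes fall outside `[f_min, f_max]` is an error.
#' @return the normalized [fmri_series()].
#' @export
normalize_amplitudes <- function(series, bounds = compute_bounds(series)) {
  stopifnot(inherits(series, "fmri_series"), inherits(bounds, "norm_bounds"))
  f <- series$amplitudes
  if (min(f) < bounds$f_min || max(f) > bounds$f_max)
    stop("series amplitudes fall outside the bounds' [f_min, f_max]")
  if (bounds$f_max == bounds$f_min) {
    f[] <- (bounds$a0 + bounds$a1) / 2
  } else {
    f <- bounds$a0 + (f - bounds$f_min) *
      (bounds$a1 - bounds$a0) / (bounds$f_max - bounds$f_min)
  }
  series$amplitudes <- f
  series
}

#' Dial the amplitude scale up or down
#'
#' Multiplies all amplitudes by `c` about their series-wide mean, isolating
#' the scale of the amplitude dimension without translating the cloud.  Used
#' to probe the two degenerate limits: dialed very high, the hyperspace cloud
#' stretches into a near-line and all loop structure dies; dialed very low,
#' the cloud collapses onto the spatial lattice whose only loop classes are
#' the low-persistence unit-square classes.
#'
#' @param series an [fmri_series()].
#' @param c positive scale factor.
#' @return the rescaled [fmri_series()].
#' @export
scale_amplitude <- function(series, c) {
  stopifnot(inherits(series, "fmri_series"))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("scale factor c must be a positive number")
  mu <- mean(series$amplitudes)
  series$amplitudes <- mu + (series$amplitudes - mu) * c
  series
}
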