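# Reading, writing and masking of per-timepoint voxel tables.
#
# The on-disk dialect is one delimited text file per time index with columns
# x, y, z, amplitude (header optional), packaged loose in a directory or in a
# ZIP archive.  Coordinates are real numbers in whatever stereotactic unit the
# source uses (voxel indices or mm); the unit is metadata only.

#' Construct a single-timepoint voxel cloud
#'
#' A `time_point_cloud` holds the voxel set of one time index: `n` spatial
#' coordinates and the signal amplitude at each.
#'
#' @param coords numeric matrix with `n` rows and 3 columns (x, y, z).
#' @param amplitude numeric vector of length `n`, the signal amplitudes.
#' @param t integer time index (`>= 0`).
#' @return An object of class `time_point_cloud`.
#' @examples
#' cl <- time_point_cloud(cbind(0:1, 0, 0), c(1.5, 2), t = 0)
#' cl
#' @export
time_point_cloud <- function(coords, amplitude, t = 0L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 1L) stop("a time point cloud must contain at least one voxel")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  amplitude <- as.double(amplitude)
  if (length(amplitude) != nrow(coords))
    stop("amplitude must have one value per coordinate row")
  if (!all(is.finite(amplitude))) stop("all amplitudes must be finite")
  if (anyDuplicated(coords))
    stop("duplicate voxel coordinates in time point cloud (t = ", t, ")")
  colnames(coords) <- c("x", "y", "z")
  structure(list(t = as.integer(t), coords = coords, amplitude = amplitude),
            class = "time_point_cloud")
}

#' @export
print.time_point_cloud <- function(x, ...) {
  cat(sprintf("<time_point_cloud> t = %d, %d voxels, amplitude range [%g, %g]\n",
              x$t, nrow(x$coords), min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' Construct an aligned multi-timepoint series
#'
#' An `fmri_series` is an ordered set of [time_point_cloud()]s sharing the
#' identical voxel coordinate set in the identical order, so that amplitude
#' dynamics can be tracked per voxel.
#'
#' @param clouds list of `time_point_cloud` objects, one per time index.
#' @return An object of class `fmri_series` with fields `coords` (n x 3),
#'   `amplitudes` (n x T matrix, one column per time index) and `t` (length-T
#'   integer vector of time indices).
#' @export
fmri_series <- function(clouds) {
  if (length(clouds) < 1L) stop("a series needs at least one time point")
  ord <- order(vapply(clouds, function(cl) cl$t, integer(1)))
  clouds <- clouds[ord]
  ref <- clouds[[1L]]$coords
  for (i in seq_along(clouds)) {
    if (!isTRUE(all.equal(clouds[[i]]$coords, ref, check.attributes = FALSE)))
      stop("time point ", clouds[[i]]$t,
           " has a different voxel coordinate set than time point ",
           clouds[[1L]]$t)
  }
  amplitudes <- vapply(clouds, function(cl) cl$amplitude,
                       numeric(nrow(ref)))
  amplitudes <- matrix(amplitudes, nrow = nrow(ref))
  structure(list(coords = ref, amplitudes = amplitudes,
                 t = vapply(clouds, function(cl) cl$t, integer(1))),
            class = "fmri_series")
}

#' @export
print.fmri_series <- function(x, ...) {
  cat(sprintf("<fmri_series> %d voxels x %d time indices (t = %d..%d)\n",
              nrow(x$coords), length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Number of time points in a series
#' @param series an [fmri_series()].
#' @return integer count of time indices.
#' @export
n_timepoints <- function(series) length(series$t)

#' Extract one time point from a series
#' @param series an [fmri_series()].
#' @param i position in the series (1..T), not the time index label.
#' @return a [time_point_cloud()].
#' @export
get_cloud <- function(series, i) {
  stopifnot(i >= 1L, i <= length(series$t))
  time_point_cloud(series$coords, series$amplitudes[, i], series$t[i])
}

#' Read one per-timepoint voxel table
#'
#' The table must have at least four numeric columns, read as x, y, z,
#' amplitude in that order; a header row naming them is accepted and ignored.
#' The time index is parsed from the trailing integer in the file name unless
#' supplied.
#'
#' @param path path to a delimited text file.
#' @param t time index; if `NULL`, parsed from the trailing integer in the
#'   file name (an error if none is present).
#' @param sep field separator, default comma.
#' @return a [time_point_cloud()]; row order of the table is preserved.
#' @export
read_timepoint_table <- function(path, t = NULL, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9eE., \t]+$", first)
  tab <- utils::read.csv(path, header = has_header, sep = sep,
                         stringsAsFactors = FALSE)
  if (nrow(tab) < 1L) stop("empty table: ", path)
  if (ncol(tab) < 4L)
    stop("table must have >= 4 columns (x, y, z, amplitude): ", path)
  tab <- tab[, 1:4]
  for (j in 1:4) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
      stop("non-numeric value in column ", j, ", row ", bad, " of ", path)
    }
  }
  if (is.null(t)) t <- parse_time_index(path)
  time_point_cloud(as.matrix(tab[, 1:3]), tab[[4L]], t)
}

parse_time_index <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(stem, regexpr("[0-9]+$", stem))
  if (length(m) != 1L || !nzchar(m))
    stop("cannot parse a time index from file name: ", basename(path),
         " (expected a trailing integer)")
  as.integer(m)
}

#' Write one per-timepoint voxel table
#'
#' @param cloud a [time_point_cloud()].
#' @param path output file path.
#' @param header write a `x,y,z,amplitude` header row?
#' @return `path`, invisibly.
#' @export
write_timepoint_table <- function(cloud, path, header = TRUE) {
  num <- cbind(cloud$coords, cloud$amplitude)
  rows <- apply(num, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  lines <- if (header) c("x,y,z,amplitude", rows) else rows
  writeLines(lines, path)
  invisible(path)
}

#' Read a full series from a directory or ZIP archive
#'
#' All `.csv` files are read as per-timepoint tables, ordered by the numeric
#' time index in their file names, and canonicalized to a common lexicographic
#' (x, y, z) voxel order so that all clouds align.
#'
#' @param path directory containing one table per time index, or a `.zip`
#'   archive of such tables.
#' @param sep field separator, default comma.
#' @return an [fmri_series()].
#' @export
read_series <- function(path, sep = ",") {
  if (length(path) == 1L && grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("fmrivine_unzip")
    utils::unzip(path, exdir = exdir)
    path <- exdir
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  }
  files <- list.files(path, pattern = "\\.(csv|txt)$", full.names = TRUE,
                      recursive = TRUE)
  if (length(files) < 1L) stop("no .csv tables found under ", path)
  idx <- vapply(files, parse_time_index, integer(1))
  if (anyDuplicated(idx))
    stop("duplicate time index in file names: ",
         basename(files[duplicated(idx)][1L]))
  files <- files[order(idx)]
  clouds <- lapply(files, function(f) read_timepoint_table(f, sep = sep))
  clouds <- lapply(clouds, canonicalize_cloud)
  ref <- clouds[[1L]]$coords
  for (i in seq_along(clouds)) {
    if (!identical(dim(clouds[[i]]$coords), dim(ref)) ||
        !isTRUE(all.equal(clouds[[i]]$coords, ref, check.attributes = FALSE)))
      stop("coordinate set mismatch across time points; first offending file: ",
           basename(files[i]))
  }
  fmri_series(clouds)
}

canonicalize_cloud <- function(cloud) {
  ord <- order(cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  time_point_cloud(cloud$coords[ord, , drop = FALSE], cloud$amplitude[ord],
                   cloud$t)
}

#' Write a full series as one table per time index
#'
#' @param series an [fmri_series()].
#' @param dir output directory (created if needed); files are named
#'   `t<k>.csv`.
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$t))
    write_timepoint_table(get_cloud(series, i),
                          file.path(dir, sprintf("t%d.csv", series$t[i])))
  invisible(dir)
}

#' Region-of-interest masks
#'
#' `mask_box()` is a closed axis-aligned box in stereotactic space;
#' `mask_voxels()` an explicit coordinate list.  Membership in a box is tested
#' per axis with closed intervals (`min <= coord <= max`).
#'
#' @param xlim,ylim,zlim length-2 numeric vectors, closed interval per axis.
#' @return an object of class `mask_region`.
#' @export
mask_box <- function(xlim, ylim, zlim) {
  for (lim in list(xlim, ylim, zlim))
    if (length(lim) != 2L || lim[1] > lim[2])
      stop("each axis limit must be c(min, max) with min <= max")
  structure(list(type = "box", xlim = as.double(xlim), ylim = as.double(ylim),
                 zlim = as.double(zlim)), class = "mask_region")
}

#' @rdname mask_box
#' @param coords numeric matrix (m x 3) of voxel coordinates to retain.
#' @export
mask_voxels <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("voxel mask must contain at least one coordinate")
  structure(list(type = "voxels", coords = coords), class = "mask_region")
}

mask_membership <- function(mask, coords) {
  if (mask$type == "box") {
    coords[, 1] >= mask$xlim[1] & coords[, 1] <= mask$xlim[2] &
      coords[, 2] >= mask$ylim[1] & coords[, 2] <= mask$ylim[2] &
      coords[, 3] >= mask$zlim[1] & coords[, 3] <= mask$zlim[2]
  } else {
    keys <- paste(coords[, 1], coords[, 2], coords[, 3])
    keys %in% paste(mask$coords[, 1], mask$coords[, 2], mask$coords[, 3])
  }
}

#' Restrict a series to a region of interest
#'
#' @param series an [fmri_series()].
#' @param mask a [mask_box()] or [mask_voxels()] region.
#' @return the masked [fmri_series()]; an error if the mask removes all
#'   voxels.  Masking is idempotent and preserves voxel alignment.
#' @export
apply_mask <- function(series, mask) {
  stopifnot(inherits(series, "fmri_series"), inherits(mask, "mask_region"))
  keep <- mask_membership(mask, series$coords)
  if (!any(keep)) stop("mask removed all voxels")
  structure(list(coords = series$coords[keep, , drop = FALSE],
                 amplitudes = series$amplitudes[keep, , drop = FALSE],
                 t = series$t), class = "fmri_series")
}

#' Read a 4-D NIfTI volume plus binary mask as a series
#'
#' Convenience adapter flattening a volumetric acquisition into the table
#' representation, with voxel indices as coordinates.  Requires the RNifti
#' package; the table path is the reference path.
#'
#' @param volume path to a 4-D NIfTI file.
#' @param mask path to a 3-D NIfTI binary mask of the same grid (optional).
#' @return an [fmri_series()].
#' @export
read_nifti_series <- function(volume, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("read_nifti_series requires the RNifti package")
  img <- RNifti::readNifti(volume)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D volume")
  keep <- array(TRUE, d[1:3])
  if (!is.null(mask)) {
    m <- RNifti::readNifti(mask)
    if (!identical(dim(m)[1:3], d[1:3])) stop("mask grid does not match volume")
    keep <- m != 0
  }
  idx <- which(keep, arr.ind = TRUE)
  clouds <- lapply(seq_len(d[4]), function(k) {
    vol <- img[, , , k]
    time_point_cloud(idx, vol[keep], t = k - 1L)
  })
  fmri_series(lapply(clouds, canonicalize_cloud))
}
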