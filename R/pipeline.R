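# Pipeline orchestration: read -> mask -> normalize -> diagrams -> vineyard
# -> vine extraction -> permutation test -> loop export, with a run manifest
# that makes every run reproducible from its recorded configuration alone.

#' Run the full vineyard pipeline
#'
#' Executes the stages in order, writing each stage's output before the next
#' begins: per-timepoint diagrams, the vineyard, ranked candidate vine
#' regions, the vine selection, the permutation test (when a design is
#' supplied) and a loop overlay table, plus a manifest recording the
#' configuration, package version, seed and per-stage wall-clock.
#'
#' @param input an [fmri_series()], or a path to a directory / ZIP archive of
#'   per-timepoint tables.
#' @param output_dir directory for stage outputs (created if needed).
#' @param mask optional [mask_box()] / [mask_voxels()] ROI applied on read.
#' @param normalize apply [normalize_amplitudes()]? Set `FALSE` for inputs
#'   that are already normalized.
#' @param r_max,max_dim,persistence_floor see [diagrams_over_time()].
#' @param d_ref,d_link see [build_vineyard()] and [rank_vines()].
#' @param region stereotactic box for [extract_vine()]; default `NULL` takes
#'   the top-ranked candidate from [rank_vines()].
#' @param min_persistence vine persistence floor; default 0.8.
#' @param design a [task_design()], or path to a design file
#'   ([read_design()]); `NULL` skips the test stage.
#' @param conditions,q,n_perm,seed see [vine_permutation_test()].
#' @return (invisibly) a list of class `fmrivine_run` with all stage results
#'   and the manifest.
#' @export
run_pipeline <- function(input, output_dir, mask = NULL, normalize = TRUE,
                         r_max = 12, max_dim = 1, persistence_floor = 0,
                         d_ref = 4, d_link = d_ref / 2, region = NULL,
                         min_persistence = 0.8, design = NULL,
                         conditions = c("encoding", "retrieval"), q = 2,
                         n_perm = 4999, seed = 0) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(input = if (is.character(input)) input else "<in-memory series>",
                 mask = !is.null(mask), normalize = normalize, r_max = r_max,
                 max_dim = max_dim, persistence_floor = persistence_floor,
                 d_ref = d_ref, d_link = d_link,
                 region = if (is.null(region)) "auto (top-ranked vine)" else
                   unclass(region),
                 min_persistence = min_persistence,
                 conditions = conditions, q = q, n_perm = n_perm, seed = seed)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", output_dir, ")", call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  series <- stage("read", {
    s <- if (inherits(input, "fmri_series")) input else read_series(input)
    if (!is.null(mask)) s <- apply_mask(s, mask)
    s
  })
  bounds <- NULL
  if (normalize) {
    series <- stage("normalize", {
      bounds <<- compute_bounds(series)
      normalize_amplitudes(series, bounds)
    })
    jsonlite::write_json(unclass(bounds), file.path(output_dir, "bounds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  diagrams <- stage("diagrams",
    diagrams_over_time(series, r_max = r_max, max_dim = max_dim,
                       persistence_floor = persistence_floor))
  write_diagrams(diagrams, file.path(output_dir, "diagrams.csv"))
  write_representatives(diagrams, file.path(output_dir, "representatives.csv"))

  vy <- stage("vineyard", build_vineyard(diagrams, d_ref = d_ref))
  write_vineyard_json(vy, file.path(output_dir, "vineyard.json"))

  candidates <- stage("vines", rank_vines(vy, d_link = d_link))
  utils::write.csv(candidates, file.path(output_dir, "vine_candidates.csv"),
                   row.names = FALSE)

  vine_region <- region
  if (is.null(vine_region)) {
    if (nrow(candidates) == 0L)
      stop("pipeline stage 'extract_vine' failed: no candidate vines; ",
           "supply a region explicitly", call. = FALSE)
    vine_region <- candidate_region(candidates, 1L)
  }
  selection <- stage("extract_vine",
    extract_vine(vy, vine_region, min_persistence = min_persistence))

  test <- NULL
  if (!is.null(design)) {
    if (is.character(design)) design <- read_design(design)
    test <- stage("vinetest",
      vine_permutation_test(selection, design, conditions = conditions,
                            n_perm = n_perm, q = q, seed = seed))
    jsonlite::write_json(
      list(statistic = test$statistic, p_value = test$p.value,
           n_permutations = test$n_permutations, seed = test$seed,
           group_labels = test$group_labels, q = q),
      file.path(output_dir, "vinetest.json"), auto_unbox = TRUE, digits = NA)
    message(sprintf("p = %.4g", test$p.value))
  }

  overlay <- NULL
  occupied <- which(vapply(selection$diagrams,
                           function(d) nrow(d$features) > 0, logical(1)))
  if (length(occupied)) {
    d <- selection$diagrams[[occupied[1L]]]
    top <- d$features$feature_id[which.max(d$features$persistence)]
    overlay <- stage("overlay",
      export_loop_overlay(series, d, top))
    utils::write.csv(overlay, file.path(output_dir, "overlay.csv"),
                     row.names = FALSE)
  }

  manifest <- list(format = "fmrivine-run-1",
                   package_version = as.character(utils::packageVersion("fmrivine")),
                   config = config, bounds = if (is.null(bounds)) NULL else
                     unclass(bounds),
                   stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(list(series = series, diagrams = diagrams,
                           vineyard = vy, candidates = candidates,
                           region = vine_region, selection = selection,
                           test = test, overlay = overlay,
                           manifest = manifest, output_dir = output_dir),
                      class = "fmrivine_run"))
}

#' @export
print.fmrivine_run <- function(x, ...) {
  cat(sprintf("<fmrivine_run> %d time indices -> %s\n",
              length(x$diagrams), x$output_dir))
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}

#' Loop overlay table for anatomical rendering
#'
#' Rows `(x, y, z, amplitude, on_loop)` for one feature's time index: every
#' voxel of the series with a 0/1 flag marking the representative loop's
#' vertex set, ready for a heat-map-plus-loop rendering.
#'
#' @param series the [fmri_series()] the diagram was computed from.
#' @param diagram the `persistence_diagram` containing the feature.
#' @param feature_id the feature; must be of dimension >= 1 (dimension-0
#'   classes have no loop).
#' @return a data frame with one row per voxel.
#' @export
export_loop_overlay <- function(series, diagram, feature_id) {
  stopifnot(inherits(series, "fmri_series"),
            inherits(diagram, "persistence_diagram"))
  i <- match(feature_id, diagram$features$feature_id)
  if (is.na(i)) stop("no feature with id ", feature_id)
  if (diagram$features$dim[i] < 1L)
    stop("feature ", feature_id, " is dimension 0 and has no loop representative")
  pos <- match(diagram$t, series$t)
  if (is.na(pos)) stop("diagram time index ", diagram$t, " not in series")
  loop <- representative(diagram, feature_id, "vertices")
  keys <- paste(series$coords[, 1], series$coords[, 2], series$coords[, 3])
  on_loop <- as.integer(keys %in% paste(loop[, 1], loop[, 2], loop[, 3]))
  data.frame(x = series$coords[, 1], y = series$coords[, 2],
             z = series$coords[, 3],
             amplitude = series$amplitudes[, pos], on_loop = on_loop)
}
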