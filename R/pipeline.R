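#' @title End-to-end analysis pipeline
#' @description Chains detection, tracking, co-localization scoring and
#'   paired-track association over one two-channel movie, and writes the
#'   standard result tables as CSV files plus a run log.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Bundles the inputs and all module parameter blocks of one pipeline run.
#' Exactly one of `movie` (an in-memory [movie_stack()]), `green_path` and
#' `red_path` (TIFF files for [load_movie()]), or `spots_path` (a
#' pre-detected spot table CSV, schema of [detect_spots()]) must be given.
#'
#' @param movie Optional [movie_stack()].
#' @param green_path,red_path Optional TIFF paths.
#' @param spots_path Optional spot-table CSV path; detection is skipped.
#' @param pixel_size_um Optional pixel-size override for [load_movie()].
#' @param out_dir Optional output directory; when given, result tables are
#'   written there.
#' @param detect A [detect_params()].
#' @param track A [track_params()].
#' @param coloc_threshold Area-overlap threshold in `(0, 1]` (default 0.5).
#' @param assoc_gate_um Association gate distance (> 0, default 2 um).
#' @param assoc_min_run Minimum association run length (>= 1, default 9).
#' @param bin_width_um Distance histogram bin width (default 0.05 um).
#' @param seed Optional integer seed (set before any stage runs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(movie = NULL, green_path = NULL, red_path = NULL,
                            spots_path = NULL, pixel_size_um = NULL,
                            out_dir = NULL,
                            detect = detect_params(),
                            track = track_params(),
                            coloc_threshold = 0.5,
                            assoc_gate_um = 2,
                            assoc_min_run = 9L,
                            bin_width_um = 0.05,
                            seed = NULL) {
  n_inputs <- (!is.null(movie)) + (!is.null(green_path)) + (!is.null(spots_path))
  if (n_inputs != 1L)
    stop("give exactly one input: movie, green_path+red_path, or spots_path",
         call. = FALSE)
  if (!is.null(green_path) && is.null(red_path))
    stop("red_path is required with green_path", call. = FALSE)
  for (p in c(green_path, red_path, spots_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  if (coloc_threshold <= 0 || coloc_threshold > 1)
    stop("coloc_threshold must be in (0, 1]", call. = FALSE)
  if (assoc_gate_um <= 0) stop("assoc_gate_um must be > 0", call. = FALSE)
  if (assoc_min_run < 1L) stop("assoc_min_run must be >= 1", call. = FALSE)
  structure(list(movie = movie, green_path = green_path,
                 red_path = red_path, spots_path = spots_path,
                 pixel_size_um = pixel_size_um, out_dir = out_dir,
                 detect = detect, track = track,
                 coloc_threshold = coloc_threshold,
                 assoc_gate_um = assoc_gate_um,
                 assoc_min_run = as.integer(assoc_min_run),
                 bin_width_um = bin_width_um, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline on one movie
#'
#' Stages: detect -> track -> coloc -> assoc. Any stage error aborts with
#' the stage name in the message; tables produced by completed stages are
#' still written (with a manifest) when `out_dir` is set. A movie without
#' qualifying associated pairs is not an error: the association tables are
#' empty and a note is logged.
#'
#' @param config A [pipeline_config()], or a [movie_stack()] /
#'   [simulate_movie()] result (run with default parameters).
#' @param ... When `config` is not a `pipeline_config`: passed on to
#'   [pipeline_config()].
#' @return A list of class `pipeline_result`: `spots`, `tracked`,
#'   `tracks` (summary), `coloc_frames`, `coloc_summary`, `pairs`,
#'   `distances`, `distance_stats` (NULL when no pair qualifies),
#'   `log` (character vector), `config`.
#' @export
run_pipeline <- function(config, ...) {
  if (inherits(config, "coloc_sim")) config <- config$movie
  if (inherits(config, "movie_stack"))
    config <- pipeline_config(movie = config, ...)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log[[length(log) + 1L]] <<- msg
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  frame_interval_s <- 1
  if (!is.null(config$spots_path)) {
    spots <- stage("detect", read_spots(config$spots_path))
    note("loaded %d pre-detected spots from %s", nrow(spots),
         config$spots_path)
  } else {
    movie <- config$movie
    if (is.null(movie))
      movie <- stage("load", load_movie(config$green_path, config$red_path,
                                        config$pixel_size_um))
    frame_interval_s <- movie$frame_interval_s
    spots <- stage("detect", detect_spots(movie, config$detect))
    note("detected %d spots over %d frames", nrow(spots), n_frames(movie))
  }

  tracked <- stage("track",
                   build_tracks(spots, config$track, frame_interval_s))
  tracks <- stage("track", track_summary(tracked, frame_interval_s))
  note("built %d tracks", nrow(tracks))

  cf <- stage("coloc", coloc_frames(spots, config$coloc_threshold))
  csum <- stage("coloc", summarize_coloc(cf))
  note("co-localization: %.1f +/- %.1f %% over %d frames",
       csum$mean_coefficient_pct, csum$sd_coefficient_pct, csum$n_frames)

  paired <- stage("assoc", find_paired_tracks(tracked, config$assoc_gate_um,
                                              config$assoc_min_run))
  dstats <- NULL
  if (nrow(paired$pairs) > 0L) {
    dstats <- stage("assoc", distance_stats(paired, config$bin_width_um))
    note("association: %d paired-track runs, pooled distance %.3f +/- %.3f um",
         dstats$n_pairs, dstats$mean_um, dstats$sd_um)
  } else {
    note("association: no track pair within %.2g um over >= %d frames",
         config$assoc_gate_um, config$assoc_min_run)
  }

  result <- structure(list(spots = spots, tracked = tracked, tracks = tracks,
                           coloc_frames = cf, coloc_summary = csum,
                           pairs = paired$pairs,
                           distances = paired$distances,
                           distance_stats = dstats,
                           log = log, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write the pipeline result tables as CSV files
#'
#' Writes `spots.csv`, `tracks.csv`, `coloc_frames.csv`,
#' `coloc_summary.csv`, `paired_tracks.csv`, `paired_distances.csv`,
#' `distance_histogram.csv` (when pairs exist), `log.txt`, and
#' `manifest.txt` listing the files written. Deterministic content for a
#' fixed result.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(result$spots, "spots.csv")
  emit(merge(result$tracked,
             result$tracks[, c("track_id", "length")], by = "track_id"),
       "tracks.csv")
  emit(result$coloc_frames, "coloc_frames.csv")
  emit(result$coloc_summary, "coloc_summary.csv")
  emit(result$pairs, "paired_tracks.csv")
  emit(result$distances, "paired_distances.csv")
  if (!is.null(result$distance_stats))
    emit(result$distance_stats$histogram, "distance_histogram.csv")
  log_path <- file.path(dir, "log.txt")
  writeLines(result$log, log_path)
  paths <- c(paths, log_path)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(basename(paths), manifest)
  invisible(c(paths, manifest))
}
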