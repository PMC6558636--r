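#' @title Movie and table input/output
#' @description Reads and writes two-channel movies as one multi-page
#'   16-bit TIFF per channel. TIFF files written by this build of the tiff
#'   library carry no calibration tags, so the physical calibration (pixel
#'   size, frame interval) travels in a plain-text sidecar file next to
#'   the images; [load_movie()] reads it back, and an explicit pixel-size
#'   override always wins.
#' @name io
NULL

MOVIE_FULL_SCALE <- 65535

#' Write a movie as two multi-page TIFFs plus a calibration sidecar
#'
#' Intensities are rounded and clamped to the 16-bit range `[0, 65535]`
#' (raw counts are stored, not rescaled). Files written:
#' `<prefix>_green.tif`, `<prefix>_red.tif`, `<prefix>_metadata.txt`.
#'
#' @param movie A [movie_stack()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"movie"`).
#' @return Invisibly, the named vector of the three paths written.
#' @export
write_movie <- function(movie, dir, prefix = "movie") {
  stopifnot(inherits(movie, "movie_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(green = file.path(dir, paste0(prefix, "_green.tif")),
             red = file.path(dir, paste0(prefix, "_red.tif")),
             metadata = file.path(dir, paste0(prefix, "_metadata.txt")))
  for (ch in c("green", "red")) {
    arr <- movie[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(f) {
      m <- round(arr[, , f])
      pmin(pmax(m, 0), MOVIE_FULL_SCALE) / MOVIE_FULL_SCALE
    })
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L,
                    compression = "deflate")
  }
  writeLines(c(sprintf("pixel_size_um=%.17g", movie$pixel_size_um),
               sprintf("frame_interval_s=%.17g", movie$frame_interval_s),
               sprintf("full_scale=%d", MOVIE_FULL_SCALE)),
             paths[["metadata"]])
  invisible(paths)
}

read_movie_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  lapply(as.list(vals), as.numeric)
}

#' Load a two-channel movie from per-channel TIFF files
#'
#' @param green_path,red_path Paths to the multi-page TIFFs.
#' @param pixel_size_um Optional pixel-size override in micrometers; when
#'   `NULL`, the calibration sidecar written by [write_movie()] is
#'   required, and a missing calibration is an error.
#' @param frame_interval_s Optional frame-interval override in seconds
#'   (default from the sidecar, else 1).
#' @return A [movie_stack()].
#' @export
load_movie <- function(green_path, red_path, pixel_size_um = NULL,
                       frame_interval_s = NULL) {
  for (p in c(green_path, red_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  sidecar_path <- sub("_green\\.tif$", "_metadata.txt", green_path)
  meta <- read_movie_sidecar(sidecar_path)
  scale <- if (!is.null(meta$full_scale)) meta$full_scale else MOVIE_FULL_SCALE
  read_channel <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (f in seq_along(pages)) {
      pg <- pages[[f]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      arr[, , f] <- pg * scale
    }
    arr
  }
  green <- read_channel(green_path)
  red <- read_channel(red_path)
  if (!identical(dim(green), dim(red)))
    stop("channel mismatch: green is ", paste(dim(green), collapse = "x"),
         ", red is ", paste(dim(red), collapse = "x"), call. = FALSE)
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(pixel_size_um))
    stop("no pixel-size calibration found for ", green_path,
         "; pass pixel_size_um explicitly", call. = FALSE)
  if (is.null(frame_interval_s))
    frame_interval_s <- if (!is.null(meta$frame_interval_s))
      meta$frame_interval_s else 1
  movie_stack(green, red, pixel_size_um, frame_interval_s)
}

#' Write the simulator's ground truth as CSV files
#'
#' @param sim A [simulate_movie()] result.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written (`objects`, `pairing`).
#' @export
write_ground_truth <- function(sim, dir, prefix = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(objects = file.path(dir, paste0(prefix, "_objects.csv")),
             pairing = file.path(dir, paste0(prefix, "_pairing.csv")))
  utils::write.csv(sim$truth, paths[["objects"]], row.names = FALSE)
  utils::write.csv(sim$pairing, paths[["pairing"]], row.names = FALSE)
  invisible(paths)
}

#' Read a spot table written by [run_pipeline()] or [utils::write.csv()]
#'
#' Validates the schema of the detection output so pre-detected spot
#' tables can enter the pipeline in place of a movie.
#'
#' @param path CSV path.
#' @return A spot data frame.
#' @export
read_spots <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "frame", "x_um", "y_um", "wx_um", "wy_um",
            "orientation_rad", "amplitude", "area_half_max_um2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("spot table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
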