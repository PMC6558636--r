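#' Two-channel calibrated movie container
#'
#' A `movie_stack` holds one 2D intensity plane per frame for each of two
#' channels ("green" and "red"), together with the physical calibration
#' needed downstream: the pixel size in micrometers and the frame interval
#' in seconds.
#'
#' Coordinate convention (used throughout the package): pixel indices are
#' 0-based, and the physical center of pixel column `j0` is
#' `(j0 + 0.5) * pixel_size_um`. Equivalently, for R's 1-based matrix column
#' `j`, the x coordinate of the pixel center is `(j - 0.5) * pixel_size_um`;
#' rows map to y the same way. All spot centers, sizes, and distances in the
#' package are expressed in micrometers under this convention.
#'
#' @param green,red Numeric arrays of dimension `c(ny, nx, n_frames)` with
#'   nonnegative intensities. Both channels must have identical dimensions.
#' @param pixel_size_um Positive pixel size in micrometers.
#' @param frame_interval_s Positive frame interval in seconds.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(green, red, pixel_size_um, frame_interval_s = 1) {
  if (length(dim(green)) == 2L) green <- array(green, c(dim(green), 1L))
  if (length(dim(red)) == 2L) red <- array(red, c(dim(red), 1L))
  if (length(dim(green)) != 3L || length(dim(red)) != 3L)
    stop("channel arrays must be ny x nx x n_frames", call. = FALSE)
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must have identical dimensions ",
         "(got ", paste(dim(green), collapse = "x"), " vs ",
         paste(dim(red), collapse = "x"), ")", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number", call. = FALSE)
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be a positive number", call. = FALSE)
  structure(
    list(green = green, red = red,
         pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "movie_stack: 2 channels, %d frames, %d x %d px (%.3g x %.3g um), %g um/px, %g s/frame\n",
    d[3], d[2], d[1], d[2] * x$pixel_size_um, d[1] * x$pixel_size_um,
    x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `movie_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$green)[3]

#' Extract one frame of one channel
#' @param movie A `movie_stack`.
#' @param channel `"green"` or `"red"`.
#' @param frame 0-based frame index.
#' @return A numeric matrix.
#' @export
get_frame <- function(movie, channel = c("green", "red"), frame = 0L) {
  channel <- match.arg(channel)
  nf <- n_frames(movie)
  if (frame < 0L || frame >= nf)
    stop("frame must be in [0, ", nf - 1L, "]", call. = FALSE)
  movie[[channel]][, , frame + 1L]
}
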