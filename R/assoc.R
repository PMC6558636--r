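#' @title Paired-track organelle association analysis
#' @description Identifies stably associated cross-channel track pairs -
#'   tracks whose fitted centers stay within a gate distance (default 2 um)
#'   over at least `min_run` consecutive frames (default 9) - and pools
#'   their per-frame inter-center distances into summary statistics and a
#'   binned distance distribution.
#' @name assoc
NULL

#' Find associated cross-channel track pairs
#'
#' For every green/red track pair with temporal overlap, computes the
#' per-frame distance between the fitted centers and extracts maximal runs
#' of consecutive frames with distance <= `gate_um`. Each maximal
#' qualifying run of length >= `min_run` becomes one paired-track record;
#' a pair interrupted and re-established yields several records, and one
#' track may pair with several opposite-channel tracks (duplicates are
#' flagged, not removed).
#'
#' @param tracked Spot table with `track_id` from [build_tracks()], both
#'   channels.
#' @param gate_um Association gate distance (default 2 um).
#' @param min_run Minimum run length in frames (default 9; set 10 to
#'   require ten consecutive frames instead).
#' @return A list with `pairs` (one row per qualifying run: `pair_id`,
#'   `green_track`, `red_track`, `start_frame`, `end_frame`, `run_length`,
#'   `mean_um`, `median_um`, `sd_um`, `duplicated_track` flag) and
#'   `distances` (long table: `pair_id`, `frame`, `distance_um`). Both
#'   tables are empty when nothing qualifies.
#' @export
find_paired_tracks <- function(tracked, gate_um = 2, min_run = 9L) {
  stopifnot(gate_um > 0, min_run >= 1L)
  empty <- list(
    pairs = data.frame(pair_id = integer(), green_track = integer(),
                       red_track = integer(), start_frame = integer(),
                       end_frame = integer(), run_length = integer(),
                       mean_um = numeric(), median_um = numeric(),
                       sd_um = numeric(), duplicated_track = logical()),
    distances = data.frame(pair_id = integer(), frame = integer(),
                           distance_um = numeric()))
  g <- tracked[tracked$channel == "green", ]
  r <- tracked[tracked$channel == "red", ]
  if (nrow(g) == 0L || nrow(r) == 0L) return(empty)
  g_ids <- unique(g$track_id); r_ids <- unique(r$track_id)
  pair_rows <- list(); dist_rows <- list()
  pid <- 0L
  for (gi in g_ids) {
    tg <- g[g$track_id == gi, ]; tg <- tg[order(tg$frame), ]
    for (ri in r_ids) {
      tr <- r[r$track_id == ri, ]; tr <- tr[order(tr$frame), ]
      f0 <- max(min(tg$frame), min(tr$frame))
      f1 <- min(max(tg$frame), max(tr$frame))
      if (f1 - f0 + 1L < min_run) next
      frames <- f0:f1
      ig <- match(frames, tg$frame); ir <- match(frames, tr$frame)
      d <- sqrt((tg$x_um[ig] - tr$x_um[ir])^2 +
                (tg$y_um[ig] - tr$y_um[ir])^2)
      runs <- rle(d <= gate_um)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values & runs$lengths >= min_run)) {
        pid <- pid + 1L
        sel <- starts[k]:ends[k]
        dd <- d[sel]
        pair_rows[[pid]] <- data.frame(
          pair_id = pid, green_track = gi, red_track = ri,
          start_frame = frames[starts[k]], end_frame = frames[ends[k]],
          run_length = length(sel),
          mean_um = mean(dd), median_um = stats::median(dd),
          sd_um = if (length(dd) > 1L) stats::sd(dd) else 0)
        dist_rows[[pid]] <- data.frame(pair_id = pid, frame = frames[sel],
                                       distance_um = dd)
      }
    }
  }
  if (pid == 0L) return(empty)
  pairs <- do.call(rbind, pair_rows)
  pairs$duplicated_track <- duplicated(pairs$green_track) |
    duplicated(pairs$green_track, fromLast = TRUE) |
    duplicated(pairs$red_track) |
    duplicated(pairs$red_track, fromLast = TRUE)
  list(pairs = pairs, distances = do.call(rbind, dist_rows))
}

#' Distance statistics over a paired-track set
#'
#' Pools all per-frame distances from the qualifying runs and returns the
#' pooled mean, sd and median, a histogram binned at `bin_width_um`, the
#' per-pair summary, and the mean of per-pair means (reported alongside
#' the pooled statistic).
#'
#' @param paired A [find_paired_tracks()] result.
#' @param bin_width_um Histogram bin width in micrometers (default 0.05).
#' @return A list of class `distance_stats`: `n_pairs`, `n_obs`,
#'   `mean_um`, `sd_um`, `median_um`, `mean_of_pair_means_um`,
#'   `histogram` (data frame `bin_lo_um`, `bin_hi_um`, `count`),
#'   `per_pair` (the pairs table), `distances` (the pooled long table).
#' @export
distance_stats <- function(paired, bin_width_um = 0.05) {
  stopifnot(bin_width_um > 0)
  if (nrow(paired$pairs) == 0L)
    stop("no qualifying track pairs; consider relaxing gate_um or min_run",
         call. = FALSE)
  d <- paired$distances$distance_um
  edges <- seq(0, (max(d) %/% bin_width_um + 1) * bin_width_um,
               by = bin_width_um)
  counts <- as.integer(table(cut(d, edges, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(
    n_pairs = nrow(paired$pairs),
    n_obs = length(d),
    mean_um = mean(d),
    sd_um = if (length(d) > 1L) stats::sd(d) else 0,
    median_um = stats::median(d),
    mean_of_pair_means_um = mean(paired$pairs$mean_um),
    histogram = data.frame(bin_lo_um = edges[-length(edges)],
                           bin_hi_um = edges[-1L], count = counts),
    per_pair = paired$pairs,
    distances = paired$distances), class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf(
    "distance_stats: %d pairs, %d observations\n  pooled %.3f +/- %.3f um (median %.3f), mean of pair means %.3f um\n",
    x$n_pairs, x$n_obs, x$mean_um, x$sd_um, x$median_um,
    x$mean_of_pair_means_um))
  invisible(x)
}
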