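#' @title Frame-to-frame linking and track building
#' @description Links detected spots across consecutive frames into tracks
#'   by globally optimal one-to-one assignment of a cost combining center
#'   distance, relative size change, and direction consistency, with a
#'   gating radius beyond which links are forbidden.
#' @name track
NULL

#' Tracking settings
#'
#' @param gate_um Gating radius per frame interval: candidate links whose
#'   center distance exceeds this are forbidden (default 2 um).
#' @param lambda_size Weight of the relative area-change term.
#' @param lambda_dir Weight of the direction-change penalty; the penalty
#'   applies only when the earlier spot has a track history. Set both
#'   lambdas to 0 for pure-distance linking.
#' @param max_gap Number of missed frames a track may bridge. The default 0
#'   means a missed detection splits the track; with `max_gap = 1`, track
#'   ends are joined to track starts two frames later (within
#'   `2 * gate_um`) and the missing frame is filled with a linearly
#'   interpolated spot flagged `interpolated`.
#' @return A list of class `track_params`.
#' @export
track_params <- function(gate_um = 2, lambda_size = 1, lambda_dir = 0.5,
                         max_gap = 0L) {
  stopifnot(gate_um > 0, lambda_size >= 0, lambda_dir >= 0, max_gap >= 0)
  structure(list(gate_um = gate_um, lambda_size = lambda_size,
                 lambda_dir = lambda_dir, max_gap = as.integer(max_gap)),
            class = "track_params")
}

link_cost_matrix <- function(spots_t, spots_t1, params, prev_dir) {
  n1 <- nrow(spots_t); n2 <- nrow(spots_t1)
  dx <- outer(spots_t1$x_um, spots_t$x_um, "-")  # n2 x n1
  dy <- outer(spots_t1$y_um, spots_t$y_um, "-")
  d <- t(sqrt(dx^2 + dy^2))                      # n1 x n2
  a1 <- spots_t$area_half_max_um2
  a2 <- spots_t1$area_half_max_um2
  size_pen <- abs(outer(a1, a2, "-")) / (outer(a1, a2, "+") / 2)
  cost <- d / params$gate_um + params$lambda_size * size_pen
  if (params$lambda_dir > 0 && !is.null(prev_dir) && any(!is.na(prev_dir))) {
    step_dir <- atan2(t(dy), t(dx))              # n1 x n2
    dpen <- (1 - cos(step_dir - prev_dir)) / 2   # recycles prev_dir by row
    dpen[is.na(dpen)] <- 0
    dpen[d == 0] <- 0                            # stationary: no direction
    cost <- cost + params$lambda_dir * dpen
  }
  cost[d > params$gate_um] <- NA                 # forbidden
  cost
}

#' Link spots of two adjacent frames
#'
#' Cost for a candidate pair = normalized center distance (distance /
#' gate) + `lambda_size` x relative area change + `lambda_dir` x
#' direction-change penalty `(1 - cos(dtheta)) / 2` (applied only when the
#' earlier spot carries a previous step direction). Pairs beyond the
#' gating radius are forbidden. The returned assignment is the globally
#' optimal one-to-one matching: it links as many allowed pairs as
#' possible at minimum total cost; remaining spots start or terminate
#' tracks. Cost ties are broken toward smaller spot indices.
#'
#' @param spots_t,spots_t1 Spot tables (rows of a [detect_spots()] result)
#'   for two adjacent frames of one channel.
#' @param params A [track_params()].
#' @param prev_dir Optional numeric vector (radians) of the previous step
#'   direction of each spot in `spots_t`; `NA` where there is no history.
#' @return Integer vector of length `nrow(spots_t)`: for each spot in the
#'   earlier frame, the row index of its partner in `spots_t1`, or `NA`.
#' @export
link_frames <- function(spots_t, spots_t1, params = track_params(),
                        prev_dir = NULL) {
  n1 <- nrow(spots_t); n2 <- nrow(spots_t1)
  if (n1 == 0L) return(integer(0))
  if (n2 == 0L) return(rep(NA_integer_, n1))
  cost <- link_cost_matrix(spots_t, spots_t1, params, prev_dir)
  # deterministic tie-break toward smaller indices
  eps <- 1e-9 * (outer(seq_len(n1) - 1L, seq_len(n2), function(i, j)
    i * n2 + j)) / (n1 * n2 + 1)
  cost <- cost + eps
  b <- 2 + 2 * params$lambda_size + params$lambda_dir  # unlink cost bound
  BIG <- 1e8
  N <- n1 + n2
  M <- matrix(BIG, N, N)
  tl <- cost; tl[is.na(tl)] <- BIG
  M[seq_len(n1), seq_len(n2)] <- tl
  M[seq_len(n1), n2 + seq_len(n1)][diag(n1) == 1] <- b
  M[n1 + seq_len(n2), seq_len(n2)][diag(n2) == 1] <- b
  M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- solve_lap(M)
  out <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- a[i]
    if (j <= n2 && !is.na(cost[i, j])) out[i] <- j
  }
  out
}

#' Build maximal tracks from a spot table
#'
#' Applies [link_frames()] over all adjacent frame pairs of each channel
#' and assigns track ids; unlinked spots start new tracks, so tracks are
#' maximal and have strictly consecutive frames. Per-step kinematics
#' (speed, direction) are added to the spot rows.
#'
#' @param spots A [detect_spots()] table (any row order; sorted internally).
#' @param params A [track_params()].
#' @param frame_interval_s Frame interval in seconds, used for speeds.
#' @return The spot table with added columns `track_id`, `speed_um_s` and
#'   `direction_rad` (step from the previous frame in the track; `NA` on
#'   the first frame of a track), and `interpolated` (only `TRUE` for
#'   gap-filled spots when `max_gap > 0`).
#' @export
build_tracks <- function(spots, params = track_params(),
                         frame_interval_s = 1) {
  spots <- spots[order(spots$channel, spots$frame, spots$x_um, spots$y_um), ]
  rownames(spots) <- NULL
  spots$track_id <- NA_integer_
  spots$speed_um_s <- NA_real_
  spots$direction_rad <- NA_real_
  spots$interpolated <- FALSE
  if (nrow(spots) == 0L) return(spots)
  next_id <- 1L
  for (ch in unique(spots$channel)) {
    ch_rows <- which(spots$channel == ch)
    frames <- sort(unique(spots$frame[ch_rows]))
    last_dir <- numeric(0)
    # start tracks for the first populated frame
    f_rows <- ch_rows[spots$frame[ch_rows] == frames[1]]
    spots$track_id[f_rows] <- next_id - 1L + seq_along(f_rows)
    next_id <- next_id + length(f_rows)
    if (length(frames) > 1L) for (k in seq_len(length(frames) - 1L)) {
      f <- frames[k]; f1 <- frames[k + 1L]
      cur <- ch_rows[spots$frame[ch_rows] == f]
      nxt <- ch_rows[spots$frame[ch_rows] == f1]
      if (f1 - f == 1L) {
        prev_dir <- spots$direction_rad[cur]
        asn <- link_frames(spots[cur, ], spots[nxt, ], params, prev_dir)
      } else {
        asn <- rep(NA_integer_, length(cur))  # gap in the frame axis
      }
      for (i in seq_along(cur)) {
        if (!is.na(asn[i])) {
          j <- nxt[asn[i]]
          spots$track_id[j] <- spots$track_id[cur[i]]
          dxy <- c(spots$x_um[j] - spots$x_um[cur[i]],
                   spots$y_um[j] - spots$y_um[cur[i]])
          spots$speed_um_s[j] <- sqrt(sum(dxy^2)) / frame_interval_s
          spots$direction_rad[j] <- atan2(dxy[2], dxy[1])
        }
      }
      new_rows <- nxt[is.na(spots$track_id[nxt])]
      if (length(new_rows) > 0L) {
        spots$track_id[new_rows] <- next_id - 1L + seq_along(new_rows)
        next_id <- next_id + length(new_rows)
      }
    }
  }
  if (params$max_gap > 0L) spots <- close_gaps(spots, params, frame_interval_s)
  spots
}

# join a track ending at frame f to a track starting at f + g + 1
# (g <= max_gap) when the end-to-start distance permits; fill the gap with
# linearly interpolated spots flagged `interpolated`
close_gaps <- function(spots, params, frame_interval_s) {
  repeat {
    ts <- track_summary(spots, frame_interval_s)
    merged <- FALSE
    for (ch in unique(ts$channel)) {
      tch <- ts[ts$channel == ch, ]
      for (ii in order(tch$end_frame)) {
        a <- tch[ii, ]
        cand <- tch[tch$start_frame > a$end_frame + 1L &
                    tch$start_frame <= a$end_frame + 1L + params$max_gap, ]
        if (nrow(cand) == 0L) next
        a_last <- spots[spots$track_id == a$track_id &
                        spots$frame == a$end_frame, ][1, ]
        d <- sqrt((cand$start_x_um - a_last$x_um)^2 +
                  (cand$start_y_um - a_last$y_um)^2)
        g <- cand$start_frame - a$end_frame  # frames spanned
        ok <- d <= params$gate_um * g
        if (!any(ok)) next
        bsel <- cand[ok, ][which.min(d[ok]), ]
        b_first <- spots[spots$track_id == bsel$track_id &
                         spots$frame == bsel$start_frame, ][1, ]
        gap_frames <- seq(a$end_frame + 1L, bsel$start_frame - 1L)
        fill <- do.call(rbind, lapply(gap_frames, function(f) {
          w <- (f - a$end_frame) / (bsel$start_frame - a$end_frame)
          row <- a_last
          row$frame <- f
          row$x_um <- (1 - w) * a_last$x_um + w * b_first$x_um
          row$y_um <- (1 - w) * a_last$y_um + w * b_first$y_um
          row$interpolated <- TRUE
          row
        }))
        spots$track_id[spots$track_id == bsel$track_id] <- a$track_id
        fill$track_id <- a$track_id
        spots <- rbind(spots, fill)
        spots <- spots[order(spots$channel, spots$frame, spots$x_um), ]
        rownames(spots) <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  spots
}

#' Summarize tracks
#'
#' @param tracked Spot table with `track_id` from [build_tracks()].
#' @param frame_interval_s Frame interval in seconds.
#' @return One row per track: `track_id`, `channel`, `start_frame`,
#'   `end_frame`, `length` (frames), `start_x_um`, `start_y_um`,
#'   `mean_diameter_um` (mean of `2 * sqrt(wx * wy)`), `mean_speed_um_s`
#'   (mean over steps; `NA` for single-frame tracks).
#' @export
track_summary <- function(tracked, frame_interval_s = 1) {
  if (nrow(tracked) == 0L) {
    return(data.frame(track_id = integer(), channel = character(),
                      start_frame = integer(), end_frame = integer(),
                      length = integer(), start_x_um = numeric(),
                      start_y_um = numeric(), mean_diameter_um = numeric(),
                      mean_speed_um_s = numeric()))
  }
  ids <- sort(unique(tracked$track_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracked[tracked$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    data.frame(track_id = id, channel = tr$channel[1],
               start_frame = min(tr$frame), end_frame = max(tr$frame),
               length = nrow(tr),
               start_x_um = tr$x_um[1], start_y_um = tr$y_um[1],
               mean_diameter_um = mean(2 * sqrt(tr$wx_um * tr$wy_um)),
               mean_speed_um_s = if (nrow(tr) > 1L)
                 mean(tr$speed_um_s[-1L]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Force track memberships from an override table
#'
#' Replaces interactive track editing: each override row names a channel,
#' a frame, and an approximate position; the nearest spot in that frame
#' (within `tol_um`) is reassigned to the given track id.
#'
#' @param tracked Spot table with `track_id`.
#' @param overrides Data frame with columns `channel`, `frame`, `x_um`,
#'   `y_um`, `track_id`.
#' @param tol_um Matching tolerance (default 0.5 um).
#' @return The spot table with reassigned track ids.
#' @export
override_tracks <- function(tracked, overrides, tol_um = 0.5) {
  for (i in seq_len(nrow(overrides))) {
    o <- overrides[i, ]
    sel <- which(tracked$channel == o$channel & tracked$frame == o$frame)
    if (length(sel) == 0L) next
    d <- sqrt((tracked$x_um[sel] - o$x_um)^2 + (tracked$y_um[sel] - o$y_um)^2)
    if (min(d) <= tol_um)
      tracked$track_id[sel[which.min(d)]] <- o$track_id
  }
  tracked
}
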