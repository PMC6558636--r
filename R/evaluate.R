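#' @title Evaluation against simulator ground truth
#' @description Matches detected spots and reconstructed tracks to the
#'   simulator's ground-truth tables, yielding recall/precision and the
#'   fraction of trajectories recovered intact.
#' @name evaluate
NULL

# optimal one-to-one matching of detected spots to truth objects within
# a gate radius; returns truth row index per detected row (NA = unmatched)
match_points <- function(det, truth, radius_um) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) return(rep(NA_integer_, nd))
  d <- sqrt(outer(det$x_um, truth$x_um, "-")^2 +
            outer(det$y_um, truth$y_um, "-")^2)
  BIG <- 1e8
  cost <- ifelse(d <= radius_um, d, BIG)
  N <- nd + nt
  M <- matrix(BIG, N, N)
  M[seq_len(nd), seq_len(nt)] <- cost
  M[seq_len(nd), nt + seq_len(nd)][diag(nd) == 1] <- radius_um + 1
  M[nd + seq_len(nt), seq_len(nt)][diag(nt) == 1] <- radius_um + 1
  M[nd + seq_len(nt), nt + seq_len(nd)] <- 0
  a <- solve_lap(M)
  out <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) if (a[i] <= nt && d[i, a[i]] <= radius_um)
    out[i] <- a[i]
  out
}

#' Detection recall and precision against ground truth
#'
#' Matches detected spots to ground-truth objects frame by frame and
#' channel by channel with an optimal one-to-one assignment gated at
#' `radius_um`. Truth objects outside the field of view are excluded from
#' the recall denominator.
#'
#' @param spots A [detect_spots()] table.
#' @param sim A [simulate_movie()] result (or a list with `truth` and
#'   `config`).
#' @param radius_um Matching radius (default 0.3 um).
#' @return One-row data frame: `n_truth`, `n_detected`, `n_matched`,
#'   `recall`, `precision`, `rmse_um` (center error over matches).
#' @export
evaluate_detection <- function(spots, sim, radius_um = 0.3) {
  truth <- sim$truth
  cfg <- sim$config
  lim <- cfg$field_size_px * cfg$pixel_size_um
  truth <- truth[truth$x_um >= 0 & truth$x_um <= lim[1] &
                 truth$y_um >= 0 & truth$y_um <= lim[2], ]
  n_truth <- nrow(truth); n_det <- nrow(spots)
  n_match <- 0L; se <- 0
  for (ch in c("green", "red")) for (f in unique(truth$frame)) {
    tt <- truth[truth$channel == ch & truth$frame == f, ]
    dd <- spots[spots$channel == ch & spots$frame == f, ]
    m <- match_points(dd, tt, radius_um)
    hit <- which(!is.na(m))
    n_match <- n_match + length(hit)
    if (length(hit) > 0L)
      se <- se + sum((dd$x_um[hit] - tt$x_um[m[hit]])^2 +
                     (dd$y_um[hit] - tt$y_um[m[hit]])^2)
  }
  data.frame(n_truth = n_truth, n_detected = n_det, n_matched = n_match,
             recall = if (n_truth > 0) n_match / n_truth else NA_real_,
             precision = if (n_det > 0) n_match / n_det else NA_real_,
             rmse_um = if (n_match > 0) sqrt(se / n_match) else NA_real_)
}

#' Fraction of ground-truth trajectories recovered intact by the linker
#'
#' Scores linking fidelity given the detections: each truth trajectory is
#' matched frame by frame (optimal one-to-one assignment within
#' `radius_um`), and its longest run of consecutive frames in which it was
#' both detected and resolvable counts as recovered intact when all its
#' spots in the run carry a single track id. A frame is resolvable when no
#' other same-channel truth object lies within `isolation_um` of the
#' trajectory: closer than that, two objects merge into one fitted blob
#' and their identities are not observable by any single-frame detector,
#' so such frames (like frames with a missed detection, which are
#' detection's failure mode, scored by [evaluate_detection()]) end a run
#' without penalizing the linker.
#'
#' @param tracked A [build_tracks()] table.
#' @param sim A [simulate_movie()] result.
#' @param radius_um Matching radius (default 0.3 um).
#' @param isolation_um Resolvability radius (default 0.65 um, the mean
#'   object diameter of the default regime).
#' @return One-row data frame: `n_trajectories`, `n_intact`,
#'   `fraction_intact`, `mean_run_length` (frames in the scored runs).
#' @export
evaluate_tracking <- function(tracked, sim, radius_um = 0.3,
                              isolation_um = 0.65) {
  truth <- sim$truth
  n_traj <- 0L; n_intact <- 0L; run_lengths <- integer(0)
  for (ch in c("green", "red")) {
    tch <- truth[truth$channel == ch, ]
    dch <- tracked[tracked$channel == ch, ]
    # optimal one-to-one truth <-> spot matching, frame by frame, so that
    # crossing objects cannot both claim the same detection
    match_row <- matrix(NA_integer_, max(tch$id, 0L), max(tch$frame + 1L, 0L))
    for (f in unique(tch$frame)) {
      tt_f <- tch[tch$frame == f, ]
      sel <- which(dch$frame == f)
      if (length(sel) == 0L) next
      m <- match_points(dch[sel, ], tt_f, radius_um)
      hit <- which(!is.na(m))
      match_row[cbind(tt_f$id[m[hit]], f + 1L)] <- sel[hit]
    }
    for (id in unique(tch$id)) {
      tt <- tch[tch$id == id, ]
      tt <- tt[order(tt$frame), ]
      n_traj <- n_traj + 1L
      rows <- match_row[id, tt$frame + 1L]
      isolated <- vapply(seq_len(nrow(tt)), function(k) {
        others <- tch[tch$frame == tt$frame[k] & tch$id != id, ]
        nrow(others) == 0L ||
          min((others$x_um - tt$x_um[k])^2 +
              (others$y_um - tt$y_um[k])^2) >= isolation_um^2
      }, logical(1))
      runs <- rle(!is.na(rows) & isolated)
      if (!any(runs$values)) next
      ends <- cumsum(runs$lengths)
      k <- which(runs$values)[which.max(runs$lengths[runs$values])]
      run <- (ends[k] - runs$lengths[k] + 1L):ends[k]
      run_lengths <- c(run_lengths, length(run))
      tid <- unique(dch$track_id[rows[run]])
      if (length(tid) == 1L) n_intact <- n_intact + 1L
    }
  }
  data.frame(n_trajectories = n_traj, n_intact = n_intact,
             fraction_intact = if (n_traj > 0) n_intact / n_traj else NA_real_,
             mean_run_length = if (length(run_lengths) > 0)
               mean(run_lengths) else NA_real_)
}
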