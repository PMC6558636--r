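# build a tracked two-channel spot table from per-frame distance series:
# green fixed at the origin-ish, red offset by d(frame) along x
tracked_pair <- function(d, frames = seq_along(d) - 1L) {
  g <- mk_spots(rep(5, length(frames)), 5, frame = 0L)
  g <- do.call(rbind, lapply(seq_along(frames), function(k) {
    r <- g[1, ]; r$frame <- frames[k]; r
  }))
  r <- g; r$channel <- "red"; r$x_um <- 5 + d
  g$track_id <- 1L; r$track_id <- 2L
  rbind(g, r)
}

test_that("constant-distance pairs qualify; gated or short runs do not", {
  p <- find_paired_tracks(tracked_pair(rep(0.5, 20)))
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$run_length, 20L)
  expect_equal(p$pairs$mean_um, 0.5)
  expect_equal(p$pairs$sd_um, 0)

  expect_equal(nrow(find_paired_tracks(tracked_pair(rep(2.5, 20)))$pairs), 0L)

  # distance dips below the gate for only 7 consecutive frames
  d <- c(rep(3, 5), rep(0.8, 7), rep(3, 8))
  expect_equal(nrow(find_paired_tracks(tracked_pair(d), min_run = 9L)$pairs),
               0L)
  expect_equal(nrow(find_paired_tracks(tracked_pair(d), min_run = 7L)$pairs),
               1L)
})

test_that("run extraction equals a brute-force scan and runs are maximal and disjoint", {
  set.seed(50)
  for (rep in 1:20) {
    nf <- sample(15:40, 1)
    d <- runif(nf, 0, 3)
    got <- find_paired_tracks(tracked_pair(d), gate_um = 2, min_run = 5L)
    want <- brute_force_runs(seq_len(nf) - 1L, d, 2, 5L)
    expect_equal(nrow(got$pairs), length(want))
    if (length(want) > 0L) {
      expect_equal(got$pairs$start_frame, vapply(want, `[`, 0, 1L))
      expect_equal(got$pairs$end_frame, vapply(want, `[`, 0, 2L))
      # maximal: frames adjacent to a run violate the gate
      for (k in seq_along(want)) {
        if (want[[k]][1] > 0) expect_gt(d[want[[k]][1]], 2)
        if (want[[k]][2] < nf - 1) expect_gt(d[want[[k]][2] + 2], 2)
      }
      # disjoint
      if (length(want) > 1L)
        expect_true(all(diff(unlist(want)) > 0))
    }
  }
})

test_that("brute-force equivalence holds over multi-track instances", {
  # several short tracks per channel with varying overlap windows
  set.seed(51)
  mk_track <- function(id, ch, f0, f1, x0, vx) {
    fr <- f0:f1
    out <- mk_spots(x0 + vx * (fr - f0), 5, frame = 0L, channel = ch)
    out$frame <- fr; out$track_id <- id
    out
  }
  tab <- rbind(mk_track(1L, "green", 0L, 24L, 3, 0.05),
               mk_track(2L, "green", 5L, 19L, 8, -0.1),
               mk_track(3L, "red", 0L, 14L, 3.5, 0.05),
               mk_track(4L, "red", 10L, 24L, 6.5, -0.05))
  got <- find_paired_tracks(tab, gate_um = 1, min_run = 4L)
  # oracle: scan every (green, red) pair over its common window
  expected <- 0L
  for (g in 1:2) for (r in 3:4) {
    tg <- tab[tab$track_id == g, ]; tr <- tab[tab$track_id == r, ]
    f0 <- max(min(tg$frame), min(tr$frame))
    f1 <- min(max(tg$frame), max(tr$frame))
    if (f0 > f1) next
    d <- abs(tg$x_um[match(f0:f1, tg$frame)] -
             tr$x_um[match(f0:f1, tr$frame)])
    expected <- expected + length(brute_force_runs(f0:f1, d, 1, 4L))
  }
  expect_equal(nrow(got$pairs), expected)
})

test_that("pooled statistics match the Rayleigh law for pure-jitter pairs", {
  d <- simulate_paired_distance_series(10, 60, 0, 0, 0.07, seed = 60)
  # route the series through the assoc pooling machinery
  tab <- do.call(rbind, lapply(split(d, d$pair), function(dd) {
    t <- tracked_pair(dd$distance_um)
    # separate the pairs in space so only true partners fall in the gate
    t$y_um <- t$y_um + 10 * dd$pair[1]
    t$track_id <- t$track_id + 2L * dd$pair[1]
    t
  }))
  got <- distance_stats(find_paired_tracks(tab))
  expect_equal(got$n_obs, 600L)
  expect_equal(got$mean_um, 0.07 * sqrt(pi), tolerance = 0.05)
  expect_equal(got$median_um, 0.07 * sqrt(2 * log(2) * 2), tolerance = 0.05)
  expect_equal(sum(got$histogram$count), got$n_obs)
})

test_that("tether-distance recovery matches the Rice mean within 0.05 um", {
  for (td in c(0.4, 0.8)) {
    d <- simulate_paired_distance_series(8, 40, td, 0, 0.05, seed = 61)
    expect_equal(mean(d$distance_um), rice_mean(td, 0.05 * sqrt(2)),
                 tolerance = 0.05)
  }
})

test_that("distance_stats demands at least one pair", {
  empty <- find_paired_tracks(tracked_pair(rep(3, 20)))
  expect_error(distance_stats(empty), "relax")
})
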