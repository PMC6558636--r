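test_that("solve_lap equals brute-force enumeration and is deterministic", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    C <- matrix(round(runif(n * n), 3), n)
    a <- solve_lap(C)
    expect_equal(sort(a), seq_len(n))  # a permutation
    best <- min(vapply(all_perms(seq_len(n)), function(p)
      sum(C[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(sum(C[cbind(seq_len(n), a)]), best, tolerance = 1e-12)
    expect_identical(a, solve_lap(C))
  }
})

test_that("a stationary spot links to itself; gated spots do not link", {
  s0 <- mk_spots(1, 1)
  expect_equal(link_frames(s0, mk_spots(1.02, 1.01, frame = 1L)), 1L)
  # displaced 3 um with a 2 um gate: no assignment
  expect_true(is.na(link_frames(s0, mk_spots(4, 1, frame = 1L))))
})

test_that("crossing spots with distinct sizes follow size continuity", {
  # two objects swap positions; area continuity must preserve identity
  big0 <- mk_spots(1.0, 1.0, w = 0.5)
  small0 <- mk_spots(2.0, 1.0, w = 0.2)
  t0 <- rbind(big0, small0)
  t1 <- rbind(mk_spots(2.0, 1.0, w = 0.5, frame = 1L),   # big moved right
              mk_spots(1.0, 1.0, w = 0.2, frame = 1L))   # small moved left
  asn <- link_frames(t0, t1, track_params())
  expect_equal(asn, c(1L, 2L))
  # pure-distance mode links by proximity instead
  asn_d <- link_frames(t0, t1, track_params(lambda_size = 0, lambda_dir = 0))
  expect_equal(asn_d, c(2L, 1L))
})

test_that("frame linking is optimal against brute force on small instances", {
  set.seed(20)
  params <- track_params(lambda_size = 1, lambda_dir = 0)
  for (rep in 1:15) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    t0 <- mk_spots(runif(n1, 0, 6), runif(n1, 0, 6), w = runif(n1, 0.2, 0.5))
    t1 <- mk_spots(runif(n2, 0, 6), runif(n2, 0, 6), w = runif(n2, 0.2, 0.5),
                   frame = 1L)
    asn <- link_frames(t0, t1, params)
    cost <- colocdyn:::link_cost_matrix(t0, t1, params, NULL)
    cost[is.na(cost)] <- Inf
    b <- 2 + 2 * params$lambda_size + params$lambda_dir
    linked <- which(!is.na(asn))
    got <- sum(cost[cbind(linked, asn[linked])]) +
      b * (n1 - length(linked)) + b * (n2 - length(linked))
    expect_equal(got, brute_force_link_cost(cost, b), tolerance = 1e-6)
  }
})

test_that("track sets are invariant to spot order within frames", {
  set.seed(30)
  sp <- do.call(rbind, lapply(0:5, function(f)
    mk_spots(runif(6, 0, 8) , runif(6, 0, 8), w = runif(6, 0.2, 0.4),
             frame = f)))
  canon <- function(tracked) {
    sets <- lapply(split(tracked, tracked$track_id), function(tr)
      paste(sort(sprintf("%d:%.6f:%.6f", tr$frame, tr$x_um, tr$y_um)),
            collapse = ";"))
    sort(unlist(sets))
  }
  t1 <- build_tracks(sp)
  t2 <- build_tracks(sp[sample(nrow(sp)), ])
  expect_identical(canon(t1), canon(t2))
})

test_that("a persistent object yields one maximal track with kinematics", {
  sp <- do.call(rbind, lapply(0:19, function(f)
    mk_spots(1 + 0.1 * f, 2, frame = f)))
  tr <- build_tracks(sp, frame_interval_s = 0.5)
  expect_equal(length(unique(tr$track_id)), 1L)
  ts <- track_summary(tr, frame_interval_s = 0.5)
  expect_equal(ts$length, 20L)
  expect_equal(tr$speed_um_s[tr$frame > 0], rep(0.2, 19), tolerance = 1e-9)
  expect_equal(tr$direction_rad[tr$frame > 0], rep(0, 19), tolerance = 1e-9)
})

test_that("a disappearance splits the track; max_gap = 1 bridges one frame", {
  sp <- do.call(rbind, lapply(c(0:9, 13:19), function(f)
    mk_spots(2, 2, frame = f)))
  tr <- build_tracks(sp)
  expect_equal(nrow(track_summary(tr)), 2L)  # no gap closing by default

  sp2 <- do.call(rbind, lapply(c(0:9, 11:19), function(f)
    mk_spots(2 + 0.05 * f, 2, frame = f)))
  split_default <- build_tracks(sp2)
  expect_equal(nrow(track_summary(split_default)), 2L)
  bridged <- build_tracks(sp2, track_params(max_gap = 1L))
  ts <- track_summary(bridged)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$length, 20L)
  expect_true(any(bridged$interpolated))
})

test_that("default regime: linker recovers resolvable trajectories intact", {
  ev <- evaluate_tracking(default_coupled_tracks(), default_coupled_sim())
  expect_gte(ev$fraction_intact, 0.9)
})

test_that("override table reassigns the nearest spot's track id", {
  sp <- rbind(mk_spots(1, 1, frame = 0L), mk_spots(1.05, 1, frame = 1L))
  tr <- build_tracks(sp)
  ov <- data.frame(channel = "green", frame = 1L, x_um = 1.05, y_um = 1,
                   track_id = 99L)
  tr2 <- override_tracks(tr, ov)
  expect_equal(tr2$track_id[tr2$frame == 1L], 99L)
})
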