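test_that("config validation rejects non-physical settings", {
  expect_error(sim_config(field_size_px = c(0L, 10L)), "field_size_px")
  expect_error(sim_config(pixel_size_um = -0.1), "pixel_size_um")
  expect_error(sim_config(mean_object_diameter_um = 0), "diameter")
  expect_error(sim_config(coloc_fraction = 1.2), "coloc_fraction")
  expect_error(sim_config(tether_distance_um = -1), "tether_distance_um")
  expect_error(sim_config(motion = list(pause_prob = 2)), "prob")
})

test_that("zero objects give pure background and an empty ground truth", {
  cfg <- sim_config(field_size_px = c(40L, 40L), n_frames = 2L,
                    n_objects_per_channel = 0L,
                    photometry = list(shot_noise = FALSE, read_noise_sd = 0),
                    seed = 1)
  sim <- simulate_movie(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$pairing), 0L)
  expect_true(all(sim$movie$green == cfg$photometry$background_level))
  expect_true(all(sim$movie$red == cfg$photometry$background_level))
})

test_that("full coupling with zero jitter puts both channels at the same centers", {
  cfg <- sim_config(field_size_px = c(80L, 80L), n_frames = 5L,
                    n_objects_per_channel = 7L,
                    coupling_mode = "colocalized", coloc_fraction = 1,
                    localization_jitter_um = 0, seed = 2)
  sim <- simulate_movie(cfg)
  g <- sim$truth[sim$truth$channel == "green", ]
  r <- sim$truth[sim$truth$channel == "red", ]
  g <- g[order(g$id, g$frame), ]; r <- r[order(r$id, r$frame), ]
  expect_equal(g$x_um, r$x_um)
  expect_equal(g$y_um, r$y_um)
  expect_equal(nrow(sim$pairing), 7L)
})

test_that("default regime renders 31 objects per channel in every frame", {
  sim <- default_coupled_sim()
  counts <- table(sim$truth$channel, sim$truth$frame)
  expect_true(all(counts == 31L))
  expect_equal(dim(sim$movie$green), c(300L, 300L, 25L))
})

test_that("identical configs and seeds give bit-identical output", {
  cfg <- sim_config(field_size_px = c(60L, 60L), n_frames = 4L,
                    n_objects_per_channel = 5L, seed = 99)
  s1 <- simulate_movie(cfg)
  s2 <- simulate_movie(cfg)
  expect_identical(s1$movie$green, s2$movie$green)
  expect_identical(s1$movie$red, s2$movie$red)
  expect_identical(s1$truth, s2$truth)
})

test_that("noiseless rendering equals the analytic profile sum", {
  cfg <- sim_config(field_size_px = c(50L, 40L), n_frames = 2L,
                    n_objects_per_channel = 4L,
                    photometry = list(shot_noise = FALSE, read_noise_sd = 0),
                    seed = 7)
  sim <- simulate_movie(cfg)
  fr <- get_frame(sim$movie, "green", 1L)
  tt <- sim$truth[sim$truth$channel == "green" & sim$truth$frame == 1L, ]
  manual <- matrix(cfg$photometry$background_level, 40, 50)
  for (i in seq_len(nrow(tt))) {
    for (r in 1:40) for (cc in 1:50) {
      dx <- (cc - 0.5) * 0.1 - tt$x_um[i]
      dy <- (r - 0.5) * 0.1 - tt$y_um[i]
      phi <- tt$orientation_rad[i]
      xr <- cos(phi) * dx + sin(phi) * dy
      yr <- -sin(phi) * dx + cos(phi) * dy
      u <- (xr / tt$wx_um[i])^2 + (yr / tt$wy_um[i])^2
      manual[r, cc] <- manual[r, cc] + tt$amplitude[i] / (1 + u)
    }
  }
  expect_lt(max(abs(fr - manual)) / mean(tt$amplitude), 1e-9)
})

test_that("stop-and-go trajectories mix pauses and runs at the set speed", {
  cfg <- sim_config(field_size_px = c(300L, 300L), n_frames = 40L,
                    n_objects_per_channel = 12L,
                    localization_jitter_um = 0, seed = 5)
  sim <- simulate_movie(cfg)
  g <- sim$truth[sim$truth$channel == "green", ]
  steps <- unlist(lapply(split(g, g$id), function(tr) {
    tr <- tr[order(tr$frame), ]
    sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  }))
  # per-frame displacement is either ~0 (pause) or <= run_speed * dt (run,
  # possibly slower around waypoint corners)
  expect_gt(mean(steps < 1e-9), 0.1)
  expect_gt(mean(steps > 0.5), 0.2)
  expect_lt(max(steps), cfg$motion$run_speed_um_s * cfg$frame_interval_s + 1e-9)
})

test_that("distance series is exact without noise and Rayleigh with it", {
  d0 <- simulate_paired_distance_series(3, 10, tether_distance_um = 0.5,
                                        seed = 1)
  expect_equal(d0$distance_um, rep(0.5, 30))

  # zero tether: distances are Rayleigh(sigma * sqrt(2)); the pooled mean
  # matches sigma * sqrt(pi) and a KS test accepts the law at alpha = 0.01
  sigma <- 0.07
  pooled <- unlist(lapply(1:10, function(s)
    simulate_paired_distance_series(10, 40, 0, 0, sigma,
                                    seed = s)$distance_um))
  expect_equal(length(pooled), 4000L)
  theory <- sigma * sqrt(pi)
  se <- stats::sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - theory), 3 * se)
  ks <- stats::ks.test(pooled, function(q)
    1 - exp(-q^2 / (2 * (sigma * sqrt(2))^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("rice_mean matches Monte-Carlo distance means", {
  set.seed(123)
  for (nu in c(0, 0.3, 0.8)) {
    s <- 0.1
    mc <- mean(sqrt(stats::rnorm(2e5, nu, s)^2 + stats::rnorm(2e5, 0, s)^2))
    expect_lt(abs(rice_mean(nu, s) - mc), 4 * s / sqrt(2e5) * 3 + 2e-3)
  }
  expect_equal(rice_mean(0.7, 0), 0.7)
  expect_equal(rice_mean(0, 1), sqrt(pi / 2))
})

test_that("series generator validates its arguments", {
  expect_error(simulate_paired_distance_series(0, 5), ">= 1")
  expect_error(simulate_paired_distance_series(2, 5, tether_distance_um = -1),
               ">= 0")
})
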