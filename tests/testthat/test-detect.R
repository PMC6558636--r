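test_that("candidate search: no structure, one spot, two spots, bad input", {
  p <- detect_params()
  expect_equal(nrow(find_candidates(matrix(7, 50, 50), p, 0.1)), 0L)
  expect_error(find_candidates(matrix(c(1, NaN, 1, 1), 2, 2), p, 0.1),
               "finite")

  one <- render_frame(
    data.frame(x_um = 2.05, y_um = 1.55, wx_um = 0.2, wy_um = 0.2,
               orientation_rad = 0, amplitude = 500),
    c(40L, 30L), 0.1, background = 10)
  cand <- find_candidates(one, p, 0.1)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$row, cand$col),
               as.vector(which(one == max(one), arr.ind = TRUE)))

  two <- render_frame(
    data.frame(x_um = c(1.55, 2.55), y_um = c(1.55, 1.55),
               wx_um = 0.2, wy_um = 0.2, orientation_rad = 0,
               amplitude = 500),
    c(40L, 30L), 0.1, background = 10)
  cand2 <- find_candidates(two, p, 0.1)
  # oracle: exhaustive strict local-maximum scan of the smoothed image
  sm <- colocdyn:::sep_smooth(two, p$smooth_sigma_px)
  n_max <- 0L
  for (r in 2:29) for (cc in 2:39) {
    nb <- sm[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (sm[r, cc] == max(nb) && sum(nb == max(nb)) == 1L) n_max <- n_max + 1L
  }
  expect_equal(nrow(cand2), 2L)
  expect_equal(n_max, 2L)
})

test_that("noiseless spot is fitted to sub-pixel accuracy with the area identity", {
  sp <- data.frame(x_um = 1.230, y_um = 0.775, wx_um = 0.2, wy_um = 0.2,
                   orientation_rad = 0, amplitude = 1000)
  fr <- render_frame(sp, c(30L, 20L), 0.1, background = 10)
  ft <- fit_lorentzian(fr, c(8L, 13L), 0.1,
                       detect_params(expected_diameter_um = 0.4))
  expect_true(ft$accepted)
  # truth center (12.30, 7.75) px; tolerance 0.05 px
  expect_lt(abs(ft$x_um - 1.230) / 0.1, 0.05)
  expect_lt(abs(ft$y_um - 0.775) / 0.1, 0.05)
  # half-max area == pi * wx * wy, and matches the generator's 2 px axes
  expect_equal(ft$area_half_max_um2, pi * ft$wx_um * ft$wy_um,
               tolerance = 1e-9)
  expect_equal(ft$area_half_max_um2, pi * 0.2^2, tolerance = 1e-3)
  expect_equal(ft$amplitude, 1000, tolerance = 1e-3)
  expect_equal(ft$background, 10, tolerance = 1e-3)
})

test_that("circular symmetry: wx == wy and orientation does not matter", {
  sp <- data.frame(x_um = 1.5, y_um = 1.5, wx_um = 0.25, wy_um = 0.25,
                   orientation_rad = 0, amplitude = 800)
  fr <- render_frame(sp, c(30L, 30L), 0.1, background = 5)
  ft_rot <- fit_lorentzian(fr, c(15L, 15L), 0.1,
                           detect_params(fit_orientation = TRUE))
  ft_axis <- fit_lorentzian(fr, c(15L, 15L), 0.1,
                            detect_params(fit_orientation = FALSE))
  expect_true(ft_rot$accepted && ft_axis$accepted)
  expect_equal(ft_rot$wx_um, ft_rot$wy_um, tolerance = 1e-4)
  expect_equal(ft_rot$fit_quality, ft_axis$fit_quality, tolerance = 1e-6)
})

test_that("an elliptical rotated spot is recovered with its orientation", {
  sp <- data.frame(x_um = 1.52, y_um = 1.48, wx_um = 0.40, wy_um = 0.18,
                   orientation_rad = 0.6, amplitude = 900)
  fr <- render_frame(sp, c(30L, 30L), 0.1, background = 20)
  ft <- fit_lorentzian(fr, c(15L, 15L), 0.1, detect_params())
  expect_true(ft$accepted)
  expect_equal(ft$wx_um, 0.40, tolerance = 1e-3)
  expect_equal(ft$wy_um, 0.18, tolerance = 1e-3)
  expect_equal(ft$orientation_rad, 0.6, tolerance = 1e-3)
})

test_that("degenerate windows are rejected, not thrown", {
  ft <- fit_lorentzian(matrix(3, 20, 20), c(10L, 10L), 0.1, detect_params())
  expect_false(ft$accepted)
  expect_match(ft$reason, "singular")
})

test_that("center error stays below 0.2 px RMS at SNR 10", {
  set.seed(21)
  errs <- replicate(12, {
    cx <- runif(1, 1.3, 1.7); cy <- runif(1, 1.3, 1.7)
    sp <- data.frame(x_um = cx, y_um = cy, wx_um = 0.3, wy_um = 0.3,
                     orientation_rad = 0, amplitude = 100)
    fr <- render_frame(sp, c(30L, 30L), 0.1, background = 50)
    noisy <- matrix(rpois(900, fr), 30, 30) + rnorm(900, 0, 5)
    ft <- fit_lorentzian(noisy, c(round(cy / 0.1), round(cx / 0.1)), 0.1,
                         detect_params(min_snr = 0))
    stopifnot(ft$accepted)
    c(ft$x_um - cx, ft$y_um - cy) / 0.1
  })
  expect_lt(sqrt(mean(errs^2)), 0.2)
})

test_that("detect_spots on empty movies and its determinism", {
  cfg <- sim_config(field_size_px = c(50L, 50L), n_frames = 2L,
                    n_objects_per_channel = 0L, seed = 3)
  sim <- simulate_movie(cfg)
  expect_equal(nrow(detect_spots(sim$movie)), 0L)

  s <- small_sim()
  expect_identical(detect_spots(s$movie), detect_spots(s$movie))
})

test_that("default regime: counts, size, recall and precision against truth", {
  sim <- default_coupled_sim()
  spots <- default_coupled_spots()
  counts <- spot_counts(spots)
  # per-frame counts within Poisson-level agreement of the true 31
  expect_true(all(abs(counts$n_green - 31) <= 3 * sqrt(31)))
  expect_true(all(abs(counts$n_red - 31) <= 3 * sqrt(31)))
  expect_lt(abs(mean(c(counts$n_green, counts$n_red)) - 31), 2)
  # mean fitted half-max diameter tracks the generator's 0.65 um
  expect_equal(mean(2 * sqrt(spots$wx_um * spots$wy_um)), 0.65,
               tolerance = 0.05)
  ev <- evaluate_detection(spots, sim)
  expect_gte(ev$recall, 0.95)
  expect_gte(ev$precision, 0.95)
  # sub-pixel localization: RMS error well under the 0.3 um match radius
  expect_lt(ev$rmse_um, 0.2 * sim$config$pixel_size_um * 10)
})
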