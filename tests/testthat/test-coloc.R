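sp <- function(x, y, wx = 1, wy = 1, phi = 0)
  list(x_um = x, y_um = y, wx_um = wx, wy_um = wy, orientation_rad = phi)

test_that("overlap fraction: identity, disjoint, closed-form lens, errors", {
  a <- sp(0, 0); b <- sp(1, 0)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(sp(0, 0, 0.3, 0.2), sp(5, 5, 0.3, 0.2)), 0)
  # two unit circles at center distance 1: lens area fraction 0.391
  lens <- circle_lens_fraction(1)
  expect_equal(lens, 0.391, tolerance = 1e-3)
  expect_equal(overlap_fraction(a, b), lens, tolerance = 0.01)
  expect_error(overlap_fraction(sp(0, 0, 0, 1), b), "degenerate")
})

test_that("intersection symmetry identity holds across random ellipses", {
  set.seed(40)
  for (rep in 1:30) {
    a <- sp(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.2, 1),
            runif(1, 0.2, 1), runif(1, 0, pi))
    b <- sp(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0.2, 1),
            runif(1, 0.2, 1), runif(1, 0, pi))
    area_a <- pi * a$wx_um * a$wy_um
    area_b <- pi * b$wx_um * b$wy_um
    ia <- overlap_fraction(a, b) * area_a
    ib <- overlap_fraction(b, a) * area_b
    expect_equal(ia, ib, tolerance = 0.01 * max(ia, 1e-12))
  }
})

test_that("frame classification: full overlap, none, cap, empty channel", {
  g <- mk_spots(seq_len(10), 1)
  r <- mk_spots(seq_len(10) + 0.01, 1, frame = 0L, channel = "red")
  full <- classify_coloc_frame(g, r)
  expect_equal(full$coefficient_basis_green, 100)
  expect_equal(full$coefficient_basis_red, 100)

  none <- classify_coloc_frame(mk_spots(1, 1), mk_spots(5, 5, channel = "red"))
  expect_equal(none$coefficient_pct, 0)

  # two green objects on one red object: n_coloc capped at min(n_g, n_r)
  g2 <- mk_spots(c(1, 1.05), 1, w = 0.3)
  r2 <- mk_spots(1.02, 1, w = 0.8, channel = "red")
  capped <- classify_coloc_frame(g2, r2)
  expect_equal(capped$n_coloc_basis_green, 1L)
  expect_lte(capped$coefficient_basis_green, 100)

  e <- classify_coloc_frame(g[0, ], r)
  expect_true(is.na(e$coefficient_pct))
})

test_that("coefficient is invariant under swapping the channel labels", {
  set.seed(41)
  g <- mk_spots(runif(8, 0, 5), runif(8, 0, 5), w = 0.3)
  r <- mk_spots(runif(6, 0, 5), runif(6, 0, 5), w = 0.35, channel = "red")
  ab <- classify_coloc_frame(g, r)
  ba <- classify_coloc_frame(r, g)
  expect_equal(ab$coefficient_basis_green, ba$coefficient_basis_red)
  expect_equal(ab$coefficient_basis_red, ba$coefficient_basis_green)
  expect_equal(ab$coefficient_pct, ba$coefficient_pct)
})

test_that("lowering the threshold never decreases a frame's coloc count", {
  set.seed(42)
  g <- mk_spots(runif(12, 0, 4), runif(12, 0, 4), w = 0.3)
  r <- mk_spots(runif(12, 0, 4), runif(12, 0, 4), w = 0.3, channel = "red")
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(thr)
    classify_coloc_frame(g, r, threshold = thr)$n_coloc_basis_green,
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("summaries average frames, exclude empty ones, and error when all are empty", {
  g <- mk_spots(1:3, 1); r <- mk_spots(1:3 + 0.01, 1, channel = "red")
  f1 <- cbind(data.frame(frame = 0L), classify_coloc_frame(g, r))
  f2 <- cbind(data.frame(frame = 1L), classify_coloc_frame(g[0, ], r))
  expect_message(s <- summarize_coloc(rbind(f1, f2)), "excluded")
  expect_equal(s$n_frames, 1L)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$mean_coefficient_pct, 100)
  expect_equal(s$sd_coefficient_pct, 0)
  expect_error(summarize_coloc(f2), "no frames")
})

test_that("known coupled fraction is recovered by the coefficient", {
  # ground-truth spot tables (no rendering): fraction f of green objects
  # gets a coincident red partner, the rest are independent
  set.seed(43)
  for (f_true in c(0.25, 0.75)) {
    coefs <- vapply(1:8, function(fr) {
      n <- 40L
      gx <- runif(n, 0, 20); gy <- runif(n, 0, 20)
      k <- round(f_true * n)
      rx <- c(gx[seq_len(k)] + rnorm(k, 0, 0.02),
              runif(n - k, 0, 20))
      ry <- c(gy[seq_len(k)] + rnorm(k, 0, 0.02),
              runif(n - k, 0, 20))
      g <- mk_spots(gx, gy, w = 0.33, frame = fr - 1L)
      r <- mk_spots(rx, ry, w = 0.33, frame = fr - 1L, channel = "red")
      classify_coloc_frame(g, r)$coefficient_pct
    }, numeric(1))
    expect_lt(abs(mean(coefs) - 100 * f_true), 10)
  }
})
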