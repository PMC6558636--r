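#' @title Sub-pixel spot detection by elliptical Lorentzian fitting
#' @description Identifies elliptic fluorescent objects per frame: candidate
#'   seeds from thresholded local maxima, then a bounded Levenberg-Marquardt
#'   fit of an elliptical Lorentzian peak around each seed, yielding
#'   sub-pixel centers and half-maximum ellipse geometry in physical units.
#' @name detect
NULL

#' Detection settings
#'
#' @param expected_diameter_um Expected mean half-maximum object diameter,
#'   used to size the fit window, the candidate separation, and the width
#'   initial value.
#' @param threshold_k Candidate threshold: local maxima must exceed the
#'   frame median plus `threshold_k` times the robust scale (MAD).
#' @param min_separation_um Minimum separation between candidate seeds;
#'   defaults to half of `expected_diameter_um`.
#' @param window_factor Fit window width as a multiple of
#'   `expected_diameter_um` (default 2.5; neighboring objects inside a
#'   window are handled by joint cluster fitting).
#' @param smooth_sigma_px Gaussian smoothing sd (pixels) applied before
#'   local-maximum search only; fits use the raw frame.
#' @param fit_orientation Fit the ellipse orientation (default); when
#'   `FALSE`, an axis-aligned ellipse is fitted.
#' @param min_width_px Lower bound on fitted half-max semi-axes, in pixels;
#'   fits at the width bounds are rejected as degenerate.
#' @param min_snr Acceptance floor on the fitted peak amplitude, in units
#'   of the frame's robust noise scale (MAD); fits below it are rejected
#'   as noise (default 10, matching the pipeline's working assumption of
#'   peak SNR >= 10).
#' @param refine_passes Number of residual passes per frame: after fitting,
#'   the fitted peaks are subtracted and the residual is searched again for
#'   candidates, recovering objects hidden by brighter close neighbors
#'   (default 1; 0 disables).
#' @param ptol Relative convergence tolerance on parameter change.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(expected_diameter_um = 0.65,
                          threshold_k = 5,
                          min_separation_um = NULL,
                          window_factor = 2.5,
                          smooth_sigma_px = 1,
                          fit_orientation = TRUE,
                          min_width_px = 0.5,
                          min_snr = 10,
                          refine_passes = 1L,
                          ptol = 1e-8,
                          maxiter = 200L) {
  if (is.null(min_separation_um)) min_separation_um <- expected_diameter_um / 2
  stopifnot(expected_diameter_um > 0, threshold_k >= 0,
            min_separation_um >= 0, window_factor > 0, min_width_px > 0,
            min_snr >= 0, refine_passes >= 0)
  structure(list(expected_diameter_um = expected_diameter_um,
                 threshold_k = threshold_k,
                 min_separation_um = min_separation_um,
                 window_factor = window_factor,
                 smooth_sigma_px = smooth_sigma_px,
                 fit_orientation = isTRUE(fit_orientation),
                 min_width_px = min_width_px,
                 min_snr = min_snr,
                 refine_passes = as.integer(refine_passes),
                 ptol = ptol, maxiter = as.integer(maxiter)),
            class = "detect_params")
}

# separable Gaussian smoothing with replicate edge padding
sep_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  m <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-m:m, 0, sigma); k <- k / sum(k)
  ny <- nrow(img); nx <- ncol(img)
  pad <- img[c(rep(1L, m), seq_len(ny), rep(ny, m)),
             c(rep(1L, m), seq_len(nx), rep(nx, m)), drop = FALSE]
  tmp <- matrix(0, ny, ncol(pad))
  for (o in -m:m) tmp <- tmp + k[o + m + 1] * pad[seq_len(ny) + m + o, , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (o in -m:m) out <- out + k[o + m + 1] * tmp[, seq_len(nx) + m + o, drop = FALSE]
  out
}

#' Find candidate spot seeds in one frame
#'
#' Local maxima of the (lightly smoothed) frame that exceed the frame
#' median plus `threshold_k` robust scale units (MAD), thinned greedily so
#' that no two seeds are closer than `min_separation_um` (brighter seeds
#' win; ties broken by row-major pixel order). Deterministic for fixed
#' input.
#'
#' @param frame 2D numeric matrix with finite values.
#' @param params A [detect_params()].
#' @param pixel_size_um Pixel size in micrometers.
#' @return Data frame with 1-based matrix indices `row`, `col` and the
#'   smoothed intensity `value`, ordered by decreasing intensity.
#' @export
find_candidates <- function(frame, params = detect_params(),
                            pixel_size_um = 0.1) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop("frame must be a non-empty 2D matrix", call. = FALSE)
  if (any(!is.finite(frame)))
    stop("frame contains non-finite values", call. = FALSE)
  ny <- nrow(frame); nx <- ncol(frame)
  s <- sep_smooth(frame, params$smooth_sigma_px)
  thr <- stats::median(s) + params$threshold_k * stats::mad(s)
  empty <- data.frame(row = integer(), col = integer(), value = numeric())
  if (ny < 3L || nx < 3L) return(empty)
  ri <- 2:(ny - 1); ci <- 2:(nx - 1)
  core <- s[ri, ci, drop = FALSE]
  ge <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ge <- ge & (core >= s[ri + dr, ci + dc, drop = FALSE])
  }
  idx <- which(ge, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  cand$value <- s[cbind(cand$row, cand$col)]
  cand <- cand[order(-cand$value, cand$row, cand$col), ]
  min_sep_px2 <- (params$min_separation_um / pixel_size_um)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ki <- which(keep)
    if (length(ki) == 0L ||
        all((cand$row[ki] - cand$row[i])^2 +
            (cand$col[ki] - cand$col[i])^2 >= min_sep_px2)) keep[i] <- TRUE
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

# model and Jacobian for a sum of K elliptical Lorentzian peaks over a
# common background; par = c(B, then per peak A, cx, cy, wx, wy[, phi])
peak_block <- function(par, k, orient) {
  pp <- 5L + orient
  par[1L + (k - 1L) * pp + seq_len(pp)]
}

lorentz_eval_k <- function(par, X, Y, K, orient) {
  val <- rep(par[1], length(X))
  for (k in seq_len(K)) {
    p <- peak_block(par, k, orient)
    phi <- if (orient) p[6] else 0
    cp <- cos(phi); sp <- sin(phi)
    dx <- X - p[2]; dy <- Y - p[3]
    xr <- cp * dx + sp * dy
    yr <- -sp * dx + cp * dy
    u <- (xr / p[4])^2 + (yr / p[5])^2
    val <- val + p[1] / (1 + u)
  }
  val
}

lorentz_jac_k <- function(par, X, Y, K, orient) {
  pp <- 5L + orient
  J <- matrix(0, length(X), 1L + K * pp)
  J[, 1] <- 1
  for (k in seq_len(K)) {
    p <- peak_block(par, k, orient)
    A <- p[1]; wx <- p[4]; wy <- p[5]
    phi <- if (orient) p[6] else 0
    cp <- cos(phi); sp <- sin(phi)
    dx <- X - p[2]; dy <- Y - p[3]
    xr <- cp * dx + sp * dy
    yr <- -sp * dx + cp * dy
    u <- (xr / wx)^2 + (yr / wy)^2
    g <- 1 / (1 + u)
    common <- -A * g^2
    o <- 1L + (k - 1L) * pp
    J[, o + 1L] <- g
    J[, o + 2L] <- common * (-2) * (cp * xr / wx^2 - sp * yr / wy^2)
    J[, o + 3L] <- common * (-2) * (sp * xr / wx^2 + cp * yr / wy^2)
    J[, o + 4L] <- common * (-2) * xr^2 / wx^3
    J[, o + 5L] <- common * (-2) * yr^2 / wy^3
    if (orient)
      J[, o + 6L] <- common * 2 * xr * yr * (1 / wx^2 - 1 / wy^2)
  }
  J
}

# joint bounded Levenberg-Marquardt fit of K peaks around K seeds on the
# union window; returns one record per seed
fit_cluster <- function(frame, seeds, pixel_size_um, params) {
  psz <- pixel_size_um
  diam_px <- params$expected_diameter_um / psz
  h <- max(3L, as.integer(round(params$window_factor * diam_px / 2)))
  K <- nrow(seeds)
  r0 <- max(1L, min(seeds[, 1]) - h); r1 <- min(nrow(frame), max(seeds[, 1]) + h)
  c0 <- max(1L, min(seeds[, 2]) - h); c1 <- min(ncol(frame), max(seeds[, 2]) + h)
  win <- frame[r0:r1, c0:c1, drop = FALSE]
  reject_all <- function(reason)
    replicate(K, list(accepted = FALSE, reason = reason), simplify = FALSE)
  if (length(win) < 9L || diff(range(win)) == 0)
    return(reject_all("singular window"))
  xs <- (c0:c1) - 0.5
  ys <- (r0:r1) - 0.5
  X <- rep(xs, each = length(ys))
  Y <- rep(ys, times = length(xs))
  z <- as.vector(win)

  orient <- params$fit_orientation
  pp <- 5L + orient
  B0 <- stats::quantile(z, 0.25, names = FALSE)
  w0 <- max(params$min_width_px * 2, diam_px / 2)
  wmax <- h
  par0 <- B0; lower <- 0; upper <- Inf
  for (k in seq_len(K)) {
    sx <- seeds[k, 2] - 0.5; sy <- seeds[k, 1] - 0.5
    A0 <- max(frame[seeds[k, 1], seeds[k, 2]] - B0, 1)
    blk0 <- c(A0, sx, sy, w0, w0)
    blo <- c(1e-9, sx - h, sy - h, params$min_width_px, params$min_width_px)
    bhi <- c(Inf, sx + h, sy + h, wmax, wmax)
    if (orient) { blk0 <- c(blk0, 0); blo <- c(blo, -2 * pi); bhi <- c(bhi, 2 * pi) }
    par0 <- c(par0, blk0); lower <- c(lower, blo); upper <- c(upper, bhi)
  }
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper,
      fn = function(p) lorentz_eval_k(p, X, Y, K, orient) - z,
      jac = function(p) lorentz_jac_k(p, X, Y, K, orient),
      control = minpack.lm::nls.lm.control(
        ptol = params$ptol, ftol = params$ptol, maxiter = params$maxiter))),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(reject_all("no convergence"))
  rms <- sqrt(mean(fit$fvec^2))
  eps <- 1e-4
  lapply(seq_len(K), function(k) {
    p <- peak_block(fit$par, k, orient)
    if (p[1] <= 0) return(list(accepted = FALSE, reason = "non-positive amplitude"))
    wx <- p[4]; wy <- p[5]
    if (wx <= params$min_width_px * (1 + eps) || wx >= wmax * (1 - eps) ||
        wy <= params$min_width_px * (1 + eps) || wy >= wmax * (1 - eps))
      return(list(accepted = FALSE, reason = "width at bounds"))
    phi <- if (orient) p[6] else 0
    if (wx < wy) { tmp <- wx; wx <- wy; wy <- tmp; phi <- phi + pi / 2 }
    phi <- phi %% pi
    list(accepted = TRUE, reason = "",
         x_um = p[2] * psz, y_um = p[3] * psz,
         wx_um = wx * psz, wy_um = wy * psz,
         orientation_rad = phi,
         amplitude = p[1], background = fit$par[1],
         area_half_max_um2 = pi * wx * wy * psz^2,
         fit_quality = rms)
  })
}

#' Fit one elliptical Lorentzian spot around a pixel seed
#'
#' Fits `I(x, y) = B + A / (1 + u)` with
#' `u = (x''/wx)^2 + (y''/wy)^2`, where `(x'', y'')` are coordinates
#' rotated by the orientation about the center; the half-maximum contour is
#' the ellipse `u = 1` with semi-axes `(wx, wy)`. The fit is a bounded
#' Levenberg-Marquardt minimization with an analytic Jacobian on a square
#' window around the seed (truncated at frame edges). Fits that fail to
#' converge, have non-positive amplitude, or end at the width bounds are
#' returned as rejections, not errors.
#'
#' @param frame 2D numeric matrix.
#' @param seed Integer pair `c(row, col)`, 1-based matrix indices.
#' @param pixel_size_um Pixel size in micrometers.
#' @param params A [detect_params()].
#' @return A list: `accepted` (logical), `reason` (`""` when accepted), and
#'   when accepted the spot fields `x_um`, `y_um`, `wx_um`, `wy_um`
#'   (semi-axes with `wx_um >= wy_um`), `orientation_rad` in `[0, pi)`,
#'   `amplitude`, `background`, `area_half_max_um2` (`pi * wx * wy`), and
#'   `fit_quality` (residual RMS; lower is better).
#' @export
fit_lorentzian <- function(frame, seed, pixel_size_um = 0.1,
                           params = detect_params()) {
  fit_cluster(frame, matrix(as.integer(seed), 1L, 2L), pixel_size_um,
              params)[[1L]]
}

# fit all candidates of one frame (cluster fitting + residual passes +
# duplicate suppression); returns spot rows without channel/frame columns
detect_frame <- function(frame, params, psz) {
  h <- max(3L, as.integer(round(
    params$window_factor * params$expected_diameter_um / psz / 2)))
  fits_to_df <- function(fits) {
    ok <- Filter(function(ft) isTRUE(ft$accepted), fits)
    if (length(ok) == 0L) return(NULL)
    do.call(rbind, lapply(ok, function(ft)
      data.frame(x_um = ft$x_um, y_um = ft$y_um,
                 wx_um = ft$wx_um, wy_um = ft$wy_um,
                 orientation_rad = ft$orientation_rad,
                 amplitude = ft$amplitude, background = ft$background,
                 area_half_max_um2 = ft$area_half_max_um2,
                 fit_quality = ft$fit_quality)))
  }
  fit_seed_set <- function(img, cand) {
    cl <- cluster_seeds(cand$row, cand$col, 2L * h)
    fits <- list()
    for (members in cl)
      fits <- c(fits, fit_cluster(img, cbind(cand$row[members],
                                             cand$col[members]), psz, params))
    fits_to_df(fits)
  }
  noise_floor <- params$min_snr * stats::mad(frame)
  cand <- find_candidates(frame, params, psz)
  if (nrow(cand) == 0L) return(empty_spot_table()[0, -(1:2)])
  df <- fit_seed_set(frame, cand)
  if (!is.null(df)) df <- df[df$amplitude >= noise_floor, , drop = FALSE]
  pass <- 0L
  while (!is.null(df) && pass < params$refine_passes) {
    pass <- pass + 1L
    resid <- subtract_peaks(frame, df, psz)
    cand2 <- find_candidates(resid, params, psz)
    if (nrow(cand2) > 0L) {
      # keep only residual candidates away from already-fitted centers
      cx <- df$x_um / psz + 0.5; cy <- df$y_um / psz + 0.5
      sep2 <- (params$min_separation_um / psz)^2
      far <- vapply(seq_len(nrow(cand2)), function(i)
        all((cand2$col[i] - cx)^2 + (cand2$row[i] - cy)^2 >= sep2),
        logical(1))
      cand2 <- cand2[far, ]
    }
    if (nrow(cand2) == 0L) break
    extra <- fit_seed_set(resid, cand2)
    if (is.null(extra)) break
    extra <- extra[extra$amplitude >= noise_floor, , drop = FALSE]
    if (nrow(extra) == 0L) break
    df <- rbind(df, extra)
  }
  if (is.null(df) || nrow(df) == 0L) return(empty_spot_table()[0, -(1:2)])
  dedupe_spots(df)
}

# subtract fitted Lorentzian peaks (no background) over local boxes
subtract_peaks <- function(frame, df, psz) {
  out <- frame
  ny <- nrow(frame); nx <- ncol(frame)
  for (k in seq_len(nrow(df))) {
    wx <- df$wx_um[k] / psz; wy <- df$wy_um[k] / psz
    cx <- df$x_um[k] / psz; cy <- df$y_um[k] / psz
    reach <- ceiling(8 * max(wx, wy))
    c0 <- max(1L, floor(cx + 0.5) - reach); c1 <- min(nx, floor(cx + 0.5) + reach)
    r0 <- max(1L, floor(cy + 0.5) - reach); r1 <- min(ny, floor(cy + 0.5) + reach)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 0.5; ys <- (r0:r1) - 0.5
    phi <- df$orientation_rad[k]
    cp <- cos(phi); sp <- sin(phi)
    dx <- xs - cx; dy <- ys - cy
    xr <- outer(dy * sp, dx * cp, "+")
    yr <- outer(dy * cp, -dx * sp, "+")
    u <- (xr / wx)^2 + (yr / wy)^2
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] - df$amplitude[k] / (1 + u)
  }
  out
}

# single-linkage grouping of candidate seeds: seeds closer than link_px
# (in either coordinate's Euclidean sense) end up in one cluster
cluster_seeds <- function(rows, cols, link_px) {
  n <- length(rows)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if ((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2 <= link_px^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# merge fits whose centers lie within half the smaller semi-axis,
# keeping the better (lower-RMS) fit
dedupe_spots <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(df$fit_quality)
  keep <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in keep) {
      lim <- 0.5 * min(df$wx_um[i], df$wy_um[i], df$wx_um[j], df$wy_um[j])
      if ((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2 < lim^2) {
        clash <- TRUE; break
      }
    }
    if (!clash) keep <- c(keep, i)
  }
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in all frames of both channels
#'
#' Runs candidate search and Lorentzian fitting on every frame of both
#' channels, suppresses duplicate fits (two fits whose centers lie within
#' half the smaller semi-axis are merged, keeping the better residual), and
#' concatenates the accepted spots.
#'
#' @param movie A [movie_stack()].
#' @param params A [detect_params()].
#' @return Data frame with one row per accepted spot: `channel`, `frame`
#'   (0-based), `x_um`, `y_um`, `wx_um`, `wy_um`, `orientation_rad`,
#'   `amplitude`, `background`, `area_half_max_um2`, `fit_quality`. An
#'   empty result is valid. Per-frame counts are available via
#'   [spot_counts()].
#' @export
detect_spots <- function(movie, params = detect_params()) {
  stopifnot(inherits(movie, "movie_stack"))
  psz <- movie$pixel_size_um
  nf <- n_frames(movie)
  rows <- list()
  for (channel in c("green", "red")) {
    for (f in seq_len(nf) - 1L) {
      df <- detect_frame(get_frame(movie, channel, f), params, psz)
      if (nrow(df) == 0L) next
      df <- cbind(data.frame(channel = channel, frame = f), df)
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (length(rows) == 0L) return(empty_spot_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_spot_table <- function() {
  data.frame(channel = character(), frame = integer(),
             x_um = numeric(), y_um = numeric(),
             wx_um = numeric(), wy_um = numeric(),
             orientation_rad = numeric(), amplitude = numeric(),
             background = numeric(), area_half_max_um2 = numeric(),
             fit_quality = numeric())
}

#' Per-frame spot counts by channel
#' @param spots A spot table from [detect_spots()].
#' @return Data frame `frame`, `n_green`, `n_red`.
#' @export
spot_counts <- function(spots) {
  if (nrow(spots) == 0L)
    return(data.frame(frame = integer(), n_green = integer(),
                      n_red = integer()))
  frames <- sort(unique(spots$frame))
  data.frame(
    frame = frames,
    n_green = vapply(frames, function(f)
      sum(spots$frame == f & spots$channel == "green"), integer(1)),
    n_red = vapply(frames, function(f)
      sum(spots$frame == f & spots$channel == "red"), integer(1)))
}
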