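#' @title Synthetic two-channel movie generator
#' @description Renders two-channel time-lapse movies of small elliptic
#'   fluorescent objects with known ground truth, emulating confocal movies
#'   of mobile organelles: stop-and-go motion along piecewise-linear paths,
#'   elliptical Lorentzian (or Gaussian) intensity profiles, Poisson shot
#'   noise and Gaussian read noise, and three inter-channel coupling
#'   regimes (co-localized, tethered, independent).
#' @name simulate
NULL

# -- trajectory machinery ----------------------------------------------------

# piecewise-linear interpolation along a waypoint polyline at arc length s
path_point <- function(wp, s) {
  seg <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  out <- matrix(NA_real_, length(s), 2)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- ifelse(seg[idx] > 0, (s - cum[idx]) / seg[idx], 0)
  out[, 1] <- wp[idx, 1] + frac * (wp[idx + 1, 1] - wp[idx, 1])
  out[, 2] <- wp[idx, 2] + frac * (wp[idx + 1, 2] - wp[idx, 2])
  out
}

# two-state (pause/run) Markov chain, started from its stationary law
sim_states <- function(nf, pause_prob, resume_prob) {
  p_run <- if (pause_prob + resume_prob > 0)
    resume_prob / (pause_prob + resume_prob) else 1
  st <- integer(nf)
  st[1] <- stats::rbinom(1, 1, p_run)
  if (nf > 1) for (t in 2:nf) {
    st[t] <- if (st[t - 1] == 1L) stats::rbinom(1, 1, 1 - pause_prob)
             else stats::rbinom(1, 1, resume_prob)
  }
  st
}

# one stop-and-go trajectory: nf x 2 matrix of true centers (um)
sim_trajectory <- function(cfg) {
  L <- cfg$field_size_px * cfg$pixel_size_um
  m <- min(cfg$margin_um, min(L) / 4)
  rand_pts <- function(n) cbind(stats::runif(n, m, L[1] - m),
                                stats::runif(n, m, L[2] - m))
  nf <- cfg$n_frames
  st <- sim_states(nf, cfg$motion$pause_prob, cfg$motion$resume_prob)
  step <- cfg$motion$run_speed_um_s * cfg$frame_interval_s * st
  arc <- c(0, cumsum(step))[seq_len(nf)]
  wp <- rand_pts(1L)
  polyline_len <- function(w) sum(sqrt(rowSums(
    (w[-1, , drop = FALSE] - w[-nrow(w), , drop = FALSE])^2)))
  need <- max(arc)
  while (nrow(wp) < 2L || polyline_len(wp) < need) {
    wp <- rbind(wp, rand_pts(max(1L, cfg$motion$path_waypoints)))
  }
  path_point(wp, arc)
}

# -- object property draws ---------------------------------------------------

draw_props <- function(cfg, n, id_offset = 0L) {
  if (n == 0L) {
    return(data.frame(id = integer(), wx_um = numeric(), wy_um = numeric(),
                      orientation_rad = numeric(), amplitude = numeric()))
  }
  sdlog <- sqrt(log1p(cfg$object_diameter_cv^2))
  d <- stats::rlnorm(n, log(cfg$mean_object_diameter_um) - sdlog^2 / 2, sdlog)
  shape_props(cfg, n, d, id_offset)
}

shape_props <- function(cfg, n, d, id_offset = 0L) {
  rho <- exp(stats::rnorm(n, 0, cfg$axis_ratio_sdlog))
  asd <- sqrt(log1p(cfg$photometry$amplitude_cv^2))
  data.frame(
    id = id_offset + seq_len(n),
    wx_um = d / 2 * sqrt(rho),
    wy_um = d / 2 / sqrt(rho),
    orientation_rad = stats::runif(n, 0, pi),
    amplitude = stats::rlnorm(n, log(cfg$photometry$amplitude_mean) - asd^2 / 2,
                              asd))
}

# -- rendering ---------------------------------------------------------------

#' Render one frame as the analytic sum of spot profiles plus background
#'
#' Evaluates, over the full pixel grid, `B + sum_k A_k * f(u_k)` where
#' `u = (x''/wx)^2 + (y''/wy)^2` in coordinates rotated by the object's
#' orientation about its center; `f(u) = 1/(1+u)` for the Lorentzian profile
#' and `2^-u` for the Gaussian one, so the half-maximum contour is the
#' ellipse `u = 1` in both cases. No noise is added here.
#'
#' @param spots Data frame with columns `x_um`, `y_um`, `wx_um`, `wy_um`,
#'   `orientation_rad`, `amplitude` (one row per object).
#' @param field_size_px Integer pair `c(nx, ny)`.
#' @param pixel_size_um Pixel size in micrometers.
#' @param background Constant background level.
#' @param profile `"lorentzian"` or `"gaussian"`.
#' @return A `ny x nx` numeric matrix.
#' @export
render_frame <- function(spots, field_size_px, pixel_size_um,
                         background = 0, profile = "lorentzian") {
  nx <- field_size_px[1]; ny <- field_size_px[2]
  psz <- pixel_size_um
  xs <- (seq_len(nx) - 0.5)  # pixel-center coordinates, px units
  ys <- (seq_len(ny) - 0.5)
  img <- matrix(background, ny, nx)
  if (nrow(spots) == 0L) return(img)
  for (k in seq_len(nrow(spots))) {
    cx <- spots$x_um[k] / psz; cy <- spots$y_um[k] / psz
    wx <- spots$wx_um[k] / psz; wy <- spots$wy_um[k] / psz
    phi <- spots$orientation_rad[k]
    if (abs(sin(phi)) < 1e-12 || abs(wx - wy) < 1e-12) {
      u <- outer(((ys - cy) / wy)^2, ((xs - cx) / wx)^2, "+")
    } else {
      c_ <- cos(phi); s_ <- sin(phi)
      dx <- xs - cx; dy <- ys - cy
      xr <- outer(dy * s_, dx * c_, "+")   # x'' =  cos(phi) dx + sin(phi) dy
      yr <- outer(dy * c_, -dx * s_, "+")  # y'' = -sin(phi) dx + cos(phi) dy
      u <- (xr / wx)^2 + (yr / wy)^2
    }
    img <- img + if (profile == "lorentzian") spots$amplitude[k] / (1 + u)
                 else spots$amplitude[k] * 2^(-u)
  }
  img
}

apply_noise <- function(img, photometry) {
  if (isTRUE(photometry$shot_noise)) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  }
  if (photometry$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, photometry$read_noise_sd)
  }
  img
}

# -- the simulator -----------------------------------------------------------

#' Simulate a two-channel movie with ground truth
#'
#' Generates object trajectories (stop-and-go motion), couples the red
#' channel to the green one according to `coupling_mode`, renders every
#' frame, and returns the movie together with a per-frame ground-truth
#' table and a cross-channel pairing table.
#'
#' Coupling regimes: in `"colocalized"` mode a fraction `coloc_fraction` of
#' green objects has a red partner at the same true position, each channel
#' perturbed independently by the isotropic localization jitter; in
#' `"tethered"` mode partners sit at distance `tether_distance_um`
#' (plus Gaussian jitter) at a slowly diffusing angle; in `"independent"`
#' mode no cross-channel constraint is imposed. Objects that wander past
#' the field edge are clipped by the field of view, not wrapped; the ground
#' truth records their true (possibly off-field) centers.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. Identical configs
#'   and seeds give bit-identical movies and tables.
#' @return A list of class `coloc_sim` with elements `movie`
#'   (a [movie_stack()]), `truth` (data frame: `frame` 0-based, `channel`,
#'   `id`, `x_um`, `y_um`, `wx_um`, `wy_um`, `orientation_rad`,
#'   `amplitude`), `pairing` (data frame: `green_id`, `red_id`,
#'   `coupling_mode`, `tether_um`), and `config`.
#' @export
simulate_movie <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_objects_per_channel
  nf <- cfg$n_frames
  n_pair <- if (cfg$coupling_mode == "independent") 0L
            else as.integer(round(cfg$coloc_fraction * n))

  # green channel: properties and trajectories
  g_props <- draw_props(cfg, n)
  g_traj <- lapply(seq_len(n), function(i) sim_trajectory(cfg))

  # red channel: coupled partners first, then independent objects
  r_props <- draw_props(cfg, 0L)
  r_traj <- list()
  pairing <- data.frame(green_id = integer(), red_id = integer(),
                        coupling_mode = character(), tether_um = numeric())
  if (n_pair > 0L) {
    g_d <- 2 * sqrt(g_props$wx_um[seq_len(n_pair)] * g_props$wy_um[seq_len(n_pair)])
    d_red <- g_d * exp(stats::rnorm(n_pair, 0, cfg$partner_size_sdlog))
    r_props <- shape_props(cfg, n_pair, d_red)
    if (cfg$coupling_mode == "colocalized") {
      r_traj <- g_traj[seq_len(n_pair)]
      tether <- rep(0, n_pair)
    } else {
      tether <- rep(cfg$tether_distance_um, n_pair)
      r_traj <- lapply(seq_len(n_pair), function(i) {
        phi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(nf - 1, 0, cfg$tether_angle_sd_rad)))
        r <- pmax(0, cfg$tether_distance_um +
                       stats::rnorm(nf, 0, cfg$tether_jitter_um))
        g_traj[[i]] + cbind(r * cos(phi), r * sin(phi))
      })
    }
    pairing <- data.frame(green_id = seq_len(n_pair), red_id = seq_len(n_pair),
                          coupling_mode = cfg$coupling_mode, tether_um = tether)
  }
  n_free <- n - n_pair
  if (n_free > 0L) {
    r_props <- rbind(r_props, draw_props(cfg, n_free, id_offset = n_pair))
    r_traj <- c(r_traj, lapply(seq_len(n_free), function(i) sim_trajectory(cfg)))
  }

  # rendered (observed) centers: true center + per-channel localization jitter
  jitter_traj <- function(traj) {
    if (cfg$localization_jitter_um == 0 || length(traj) == 0L) return(traj)
    lapply(traj, function(tr)
      tr + matrix(stats::rnorm(2 * nf, 0, cfg$localization_jitter_um), nf, 2))
  }
  g_obs <- jitter_traj(g_traj)
  r_obs <- jitter_traj(r_traj)

  truth_channel <- function(props, obs, channel) {
    if (nrow(props) == 0L) {
      return(data.frame(frame = integer(), channel = character(),
                        id = integer(), x_um = numeric(), y_um = numeric(),
                        wx_um = numeric(), wy_um = numeric(),
                        orientation_rad = numeric(), amplitude = numeric()))
    }
    do.call(rbind, lapply(seq_len(nrow(props)), function(i) {
      data.frame(frame = seq_len(nf) - 1L, channel = channel,
                 id = props$id[i],
                 x_um = obs[[i]][, 1], y_um = obs[[i]][, 2],
                 wx_um = props$wx_um[i], wy_um = props$wy_um[i],
                 orientation_rad = props$orientation_rad[i],
                 amplitude = props$amplitude[i])
    }))
  }
  truth <- rbind(truth_channel(g_props, g_obs, "green"),
                 truth_channel(r_props, r_obs, "red"))
  truth <- truth[order(truth$channel, truth$frame, truth$id), ]
  rownames(truth) <- NULL

  # render + noise, frame-major, green then red within each frame
  nx <- cfg$field_size_px[1]; ny <- cfg$field_size_px[2]
  green <- array(0, c(ny, nx, nf)); red <- array(0, c(ny, nx, nf))
  bg <- cfg$photometry$background_level
  for (f in seq_len(nf)) {
    fg <- truth[truth$frame == f - 1L & truth$channel == "green", ]
    fr <- truth[truth$frame == f - 1L & truth$channel == "red", ]
    green[, , f] <- apply_noise(
      render_frame(fg, cfg$field_size_px, cfg$pixel_size_um, bg, cfg$profile),
      cfg$photometry)
    red[, , f] <- apply_noise(
      render_frame(fr, cfg$field_size_px, cfg$pixel_size_um, bg, cfg$profile),
      cfg$photometry)
  }
  movie <- movie_stack(green, red, cfg$pixel_size_um, cfg$frame_interval_s)
  structure(list(movie = movie, truth = truth, pairing = pairing,
                 config = cfg),
            class = "coloc_sim")
}

#' @export
print.coloc_sim <- function(x, ...) {
  cat(sprintf("coloc_sim: %s coupling, %d objects/channel, %d frames\n",
              x$config$coupling_mode, x$config$n_objects_per_channel,
              x$config$n_frames))
  print(x$movie)
  invisible(x)
}

#' Directly simulate observed inter-center distance series for tethered pairs
#'
#' Bypasses rendering and detection: for each pair, the red partner sits at
#' a (jittered) tether length from the green object at a slowly diffusing
#' angle, and both channels receive independent isotropic per-axis
#' localization noise. The observed distance is then Rice-distributed with
#' noncentrality equal to the instantaneous true separation and scale
#' `localization_jitter_um * sqrt(2)`; with zero tether it reduces to a
#' Rayleigh law.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param n_frames Frames per pair (>= 1).
#' @param tether_distance_um Mean true separation (>= 0).
#' @param tether_jitter_um Gaussian sd of the per-frame tether length.
#' @param localization_jitter_um Per-axis, per-channel localization noise sd.
#' @param tether_angle_sd_rad Angle random-walk step sd (does not affect the
#'   distance law; kept for realism of the underlying geometry).
#' @param seed Optional integer seed.
#' @return Data frame: `pair`, `frame` (0-based), `true_separation_um`,
#'   `distance_um`.
#' @export
simulate_paired_distance_series <- function(n_pairs, n_frames,
                                            tether_distance_um = 0,
                                            tether_jitter_um = 0,
                                            localization_jitter_um = 0,
                                            tether_angle_sd_rad = 0.3,
                                            seed = NULL) {
  if (n_pairs < 1L || n_frames < 1L)
    stop("n_pairs and n_frames must be >= 1", call. = FALSE)
  if (tether_distance_um < 0 || tether_jitter_um < 0 ||
      localization_jitter_um < 0)
    stop("distances and jitters must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- lapply(seq_len(n_pairs), function(p) {
    phi <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    stats::rnorm(n_frames - 1, 0, tether_angle_sd_rad)))
    r <- pmax(0, tether_distance_um +
                   stats::rnorm(n_frames, 0, tether_jitter_um))
    eps <- matrix(stats::rnorm(4 * n_frames, 0, localization_jitter_um),
                  n_frames, 4)
    dx <- r * cos(phi) + eps[, 3] - eps[, 1]
    dy <- r * sin(phi) + eps[, 4] - eps[, 2]
    data.frame(pair = p, frame = seq_len(n_frames) - 1L,
               true_separation_um = r,
               distance_um = sqrt(dx^2 + dy^2))
  })
  do.call(rbind, out)
}

#' Mean of the Rice distribution
#'
#' Closed-form mean of the Euclidean distance between two points whose true
#' separation is `nu` and whose per-component Gaussian noise has sd `sigma`:
#' `E[d] = sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2))`, evaluated via
#' exponentially scaled Bessel functions. With `nu = 0` this is the
#' Rayleigh mean `sigma * sqrt(pi/2)`.
#'
#' @param nu True separation (noncentrality), >= 0.
#' @param sigma Rice scale parameter (per-component noise sd), >= 0.
#' @return The mean distance.
#' @export
rice_mean <- function(nu, sigma) {
  if (any(nu < 0) || any(sigma < 0)) stop("nu and sigma must be >= 0")
  out <- numeric(length(nu * sigma))
  nu <- rep_len(nu, length(out)); sigma <- rep_len(sigma, length(out))
  z <- sigma == 0
  out[z] <- nu[z]
  if (any(!z)) {
    x <- nu[!z]^2 / (2 * sigma[!z]^2)
    # L_{1/2}(-x) = e^{-x/2} [ (1+x) I0(x/2) + x I1(x/2) ]
    lag <- (1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
           x * besselI(x / 2, 1, expon.scaled = TRUE)
    out[!z] <- sigma[!z] * sqrt(pi / 2) * lag
  }
  out
}
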