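#' Configuration for the synthetic two-channel movie generator
#'
#' Builds and validates the full parameter set of the simulator. Defaults
#' emulate the acquisition regime of the confocal movies the pipeline was
#' designed for: a 30 x 30 um field at 0.1 um/px, 25 frames, 31 objects per
#' channel per frame, and a mean half-maximum object diameter of 0.65 um.
#'
#' @param field_size_px Integer pair `c(nx, ny)`: field width and height in
#'   pixels.
#' @param pixel_size_um Pixel size in micrometers.
#' @param n_frames Number of frames.
#' @param frame_interval_s Frame interval in seconds.
#' @param n_objects_per_channel Objects rendered per channel in every frame.
#' @param mean_object_diameter_um Mean half-maximum diameter of the objects,
#'   in micrometers; individual diameters are lognormal with coefficient of
#'   variation `object_diameter_cv`.
#' @param object_diameter_cv Coefficient of variation of object diameters.
#' @param axis_ratio_sdlog Lognormal sd of the semi-axis ratio; 0 gives
#'   circular objects.
#' @param coupling_mode `"independent"` (the two channels are placed with no
#'   cross-channel constraint), `"colocalized"` (a fraction `coloc_fraction`
#'   of green objects has a red partner at the same true position), or
#'   `"tethered"` (partners sit at a fixed mean distance at a slowly
#'   diffusing angle).
#' @param coloc_fraction Fraction of green objects that receive a coupled
#'   red partner (used by both coupled modes).
#' @param tether_distance_um Mean tether length in tethered mode.
#' @param tether_jitter_um Per-frame Gaussian sd of the tether length.
#' @param tether_angle_sd_rad Per-frame sd of the tether angle random walk.
#' @param localization_jitter_um Isotropic per-axis, per-channel, per-frame
#'   Gaussian jitter applied to every rendered center, emulating apparent
#'   localization noise between channels.
#' @param partner_size_sdlog Lognormal sd linking a coupled partner's
#'   diameter to its green object's diameter (coupled compartments have
#'   correlated apparent size).
#' @param motion List: `run_speed_um_s`, `pause_prob` (per-frame run->pause
#'   transition probability), `resume_prob` (pause->run), `path_waypoints`
#'   (waypoints drawn per path segment batch). Produces stop-and-go motion
#'   along piecewise-linear paths.
#' @param photometry List: `amplitude_mean`, `amplitude_cv` (lognormal peak
#'   amplitude above background, per object), `background_level`,
#'   `read_noise_sd` (additive Gaussian), `shot_noise` (logical; Poisson
#'   noise on signal + background).
#' @param profile Spot profile rendered: `"lorentzian"` (the model the
#'   detector fits) or `"gaussian"` (to probe model mismatch). Both share
#'   the same half-maximum ellipse parameterization.
#' @param margin_um Path waypoints are kept this far from the field border.
#' @param seed Optional integer seed stored in the config; `simulate_movie`
#'   seeds the RNG with it when present.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_size_px = c(300L, 300L),
                       pixel_size_um = 0.1,
                       n_frames = 25L,
                       frame_interval_s = 1,
                       n_objects_per_channel = 31L,
                       mean_object_diameter_um = 0.65,
                       object_diameter_cv = 0.2,
                       axis_ratio_sdlog = 0.1,
                       coupling_mode = c("independent", "colocalized", "tethered"),
                       coloc_fraction = 1,
                       tether_distance_um = 0.5,
                       tether_jitter_um = 0.05,
                       tether_angle_sd_rad = 0.3,
                       localization_jitter_um = 0.03,
                       partner_size_sdlog = 0.1,
                       motion = list(),
                       photometry = list(),
                       profile = c("lorentzian", "gaussian"),
                       margin_um = 1,
                       seed = NULL) {
  coupling_mode <- match.arg(coupling_mode)
  profile <- match.arg(profile)
  motion_def <- list(run_speed_um_s = 1.0, pause_prob = 0.3,
                     resume_prob = 0.3, path_waypoints = 4L)
  photometry_def <- list(amplitude_mean = 1000, amplitude_cv = 0.2,
                         background_level = 100, read_noise_sd = 5,
                         shot_noise = TRUE)
  motion <- utils::modifyList(motion_def, motion)
  photometry <- utils::modifyList(photometry_def, photometry)

  cfg <- list(field_size_px = as.integer(field_size_px),
              pixel_size_um = pixel_size_um,
              n_frames = as.integer(n_frames),
              frame_interval_s = frame_interval_s,
              n_objects_per_channel = as.integer(n_objects_per_channel),
              mean_object_diameter_um = mean_object_diameter_um,
              object_diameter_cv = object_diameter_cv,
              axis_ratio_sdlog = axis_ratio_sdlog,
              coupling_mode = coupling_mode,
              coloc_fraction = coloc_fraction,
              tether_distance_um = tether_distance_um,
              tether_jitter_um = tether_jitter_um,
              tether_angle_sd_rad = tether_angle_sd_rad,
              localization_jitter_um = localization_jitter_um,
              partner_size_sdlog = partner_size_sdlog,
              motion = motion,
              photometry = photometry,
              profile = profile,
              margin_um = margin_um,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  if (length(cfg$field_size_px) != 2L || any(!is.finite(cfg$field_size_px)) ||
      any(cfg$field_size_px < 1L))
    fail("field_size_px must be two positive integers")
  if (!is.finite(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    fail("pixel_size_um must be > 0")
  if (cfg$n_frames < 1L) fail("n_frames must be >= 1")
  if (cfg$frame_interval_s <= 0) fail("frame_interval_s must be > 0")
  if (cfg$n_objects_per_channel < 0L) fail("n_objects_per_channel must be >= 0")
  if (cfg$mean_object_diameter_um <= 0) fail("mean_object_diameter_um must be > 0")
  if (cfg$object_diameter_cv < 0) fail("object_diameter_cv must be >= 0")
  if (cfg$coloc_fraction < 0 || cfg$coloc_fraction > 1)
    fail("coloc_fraction must be in [0, 1]")
  if (cfg$tether_distance_um < 0) fail("tether_distance_um must be >= 0")
  if (cfg$tether_jitter_um < 0) fail("tether_jitter_um must be >= 0")
  if (cfg$localization_jitter_um < 0) fail("localization_jitter_um must be >= 0")
  if (cfg$motion$run_speed_um_s < 0) fail("run_speed_um_s must be >= 0")
  if (cfg$motion$pause_prob < 0 || cfg$motion$pause_prob > 1 ||
      cfg$motion$resume_prob < 0 || cfg$motion$resume_prob > 1)
    fail("pause_prob and resume_prob must be probabilities")
  if (cfg$photometry$amplitude_mean <= 0) fail("amplitude_mean must be > 0")
  if (cfg$photometry$background_level < 0) fail("background_level must be >= 0")
  if (cfg$photometry$read_noise_sd < 0) fail("read_noise_sd must be >= 0")
  invisible(cfg)
}
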