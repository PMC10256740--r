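#' Motion model for simulated RNP granules
#'
#' Describes the stochastic motion of a single granule class. Five regimes
#' are supported, matching the behaviours seen in live-cell imaging of RNP
#' granules: `stationary` (anchored), `brownian` (free diffusion with
#' coefficient `D`), `directed` (processive motor-driven transport at speed
#' `v`), `confined` (diffusion reflected inside a corral of radius
#' `corral_radius` about the anchor point, the simplest model that saturates
#' the MSD), and `switching` (alternation between a diffusive and a directed
#' state with exponential dwell times).
#'
#' For `directed` and `switching` models each track draws its own constant
#' speed from a zero-truncated normal with mean `v` and standard deviation
#' `v_sd`; the parent mean is calibrated so the truncated distribution's mean
#' equals `v`. This reproduces the per-track heterogeneity of granule
#' velocity summaries.
#'
#' @param kind one of `"stationary"`, `"brownian"`, `"directed"`,
#'   `"confined"`, `"switching"`.
#' @param D diffusion coefficient, um^2/s (brownian, confined, switching).
#' @param v speed, um/s (directed, switching).
#' @param v_sd per-track SD of speed, um/s (default 0: all tracks at `v`).
#' @param heading direction of directed motion, radians; `NA` draws one
#'   uniformly per track.
#' @param corral_radius confinement radius, um (confined only).
#' @param switch_rates length-2 numeric, per-second rates out of the
#'   diffusive and directed states (switching only).
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(kind = c("stationary", "brownian", "directed",
                                  "confined", "switching"),
                         D = NULL, v = NULL, v_sd = 0, heading = NA_real_,
                         corral_radius = NULL, switch_rates = NULL) {
  kind <- match.arg(kind)
  needs_D <- kind %in% c("brownian", "confined", "switching")
  needs_v <- kind %in% c("directed", "switching")
  if (needs_D) {
    stop_arg(!is.null(D) && is.finite(D) && D >= 0,
             sprintf("motion model '%s' requires D >= 0", kind))
  } else D <- NULL
  if (needs_v) {
    stop_arg(!is.null(v) && is.finite(v) && v >= 0,
             sprintf("motion model '%s' requires v >= 0", kind))
    stop_arg(is.finite(v_sd) && v_sd >= 0, "v_sd must be >= 0")
  } else {
    v <- NULL
    v_sd <- NULL
  }
  if (kind == "confined") {
    stop_arg(!is.null(corral_radius) && corral_radius > 0,
             "confined motion requires corral_radius > 0")
  } else corral_radius <- NULL
  if (kind == "switching") {
    stop_arg(!is.null(switch_rates) && length(switch_rates) == 2L &&
               all(switch_rates >= 0),
             "switching motion requires two non-negative switch_rates")
  } else switch_rates <- NULL
  structure(list(kind = kind, D = D, v = v, v_sd = v_sd, heading = heading,
                 corral_radius = corral_radius, switch_rates = switch_rates),
            class = "motion_model")
}

#' Image acquisition settings for simulation and rendering
#'
#' Defaults follow the live-imaging regime used for granule dynamics:
#' acquisition at 10 frames per second for 60 s (`frame_interval = 0.1` s,
#' `n_frames = 600`), 0.1 um pixels, and a PSF sigma consistent with a
#' ~0.5 um diameter diffraction-limited granule. Spot amplitude and
#' background are in photon counts so Poisson shot noise is meaningful.
#'
#' @param nx,ny field of view, pixels.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames.
#' @param psf_sigma PSF standard deviation, um.
#' @param spot_amplitude peak spot intensity above background, photons.
#' @param background constant background level, photons.
#' @param noise `"none"`, `"poisson"` (shot noise on signal + background) or
#'   `"gaussian"` (additive read noise of SD `noise_sd`).
#' @param noise_sd gaussian read-noise SD, photons.
#' @param seed integer seed controlling all randomness of the generator
#'   using this spec; `NULL` uses the current RNG stream.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(nx = 128, ny = 128, pixel_size = 0.1,
                             frame_interval = 0.1, n_frames = 600,
                             psf_sigma = 0.18, spot_amplitude = 200,
                             background = 10,
                             noise = c("poisson", "gaussian", "none"),
                             noise_sd = 2, seed = NULL) {
  noise <- match.arg(noise)
  stop_arg(nx >= 1 && ny >= 1 && n_frames >= 1, "image dimensions must be positive")
  stop_arg(pixel_size > 0, "pixel_size must be > 0")
  stop_arg(frame_interval > 0, "frame_interval must be > 0")
  stop_arg(psf_sigma > 0, "psf_sigma must be > 0")
  stop_arg(spot_amplitude >= 0 && background >= 0,
           "spot_amplitude and background must be >= 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), psf_sigma = psf_sigma,
                 spot_amplitude = spot_amplitude, background = background,
                 noise = noise, noise_sd = noise_sd, seed = seed),
            class = "acquisition_spec")
}

# Field-of-view extent in um. Pixel centres sit at integer pixel coordinates
# (origin top-left, x rightward, y downward); physical um = pixel * pixel_size.
fov_um <- function(acq) c(x = (acq$nx - 1) * acq$pixel_size,
                          y = (acq$ny - 1) * acq$pixel_size)

# Fold a coordinate into [0, w] by reflection (triangle wave).
reflect_into <- function(x, w) {
  if (w <= 0) return(rep(0, length(x)))
  m <- x %% (2 * w)
  ifelse(m > w, 2 * w - m, m)
}
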