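#' Render a track set into a synthetic fluorescence movie
#'
#' Each spot is drawn as an isotropic 2-D Gaussian with standard deviation
#' `acq$psf_sigma` and peak amplitude `acq$spot_amplitude` over a constant
#' `acq$background`, then the requested noise is applied (Poisson shot noise
#' on signal + background, or additive Gaussian read noise). Pixel centres
#' are at integer pixel coordinates, origin top-left.
#'
#' @param tracks a `track_set` whose time base matches `acq` (same frame
#'   interval, frames within `0:(n_frames-1)`).
#' @param acq an [acquisition_spec()].
#' @return a `movie_stack`: list with `frames` (array ny x nx x T),
#'   `pixel_size`, `frame_interval`, `channel`.
#' @export
render_movie <- function(tracks, acq) {
  stopifnot(inherits(tracks, "track_set"), inherits(acq, "acquisition_spec"))
  if (abs(tracks$frame_interval - acq$frame_interval) > 1e-12)
    stop("track time base (frame_interval) does not match acquisition spec",
         call. = FALSE)
  tb <- tracks$tracks
  if (nrow(tb) > 0 && (min(tb$frame) < 0 || max(tb$frame) > acq$n_frames - 1))
    stop("track frames fall outside the acquisition's frame range",
         call. = FALSE)
  fov <- fov_um(acq)
  if (nrow(tb) > 0 &&
      (any(tb$x_um < -1e-9) || any(tb$x_um > fov["x"] + 1e-9) ||
       any(tb$y_um < -1e-9) || any(tb$y_um > fov["y"] + 1e-9)))
    stop("track positions fall outside the field of view", call. = FALSE)

  frames <- array(acq$background, dim = c(acq$ny, acq$nx, acq$n_frames))
  sig_px <- acq$psf_sigma / acq$pixel_size
  half <- ceiling(4 * sig_px)
  if (nrow(tb) > 0) {
    by_frame <- split(tb, tb$frame)
    for (fr in names(by_frame)) {
      t_idx <- as.integer(fr) + 1L
      sp <- by_frame[[fr]]
      for (s in seq_len(nrow(sp))) {
        cx <- sp$x_um[s] / acq$pixel_size  # 0-based pixel coords
        cy <- sp$y_um[s] / acq$pixel_size
        ix <- max(0, floor(cx - half)):min(acq$nx - 1, ceiling(cx + half))
        iy <- max(0, floor(cy - half)):min(acq$ny - 1, ceiling(cy + half))
        gx <- exp(-(ix - cx)^2 / (2 * sig_px^2))
        gy <- exp(-(iy - cy)^2 / (2 * sig_px^2))
        frames[iy + 1L, ix + 1L, t_idx] <- frames[iy + 1L, ix + 1L, t_idx] +
          acq$spot_amplitude * outer(gy, gx)
      }
    }
  }
  frames <- with_seed(derive_seed(acq$seed, "render"), switch(acq$noise,
    none = frames,
    poisson = array(stats::rpois(length(frames), frames), dim = dim(frames)),
    gaussian = frames + array(stats::rnorm(length(frames), 0, acq$noise_sd),
                              dim = dim(frames))))
  movie_stack(frames, pixel_size = acq$pixel_size,
              frame_interval = acq$frame_interval)
}

#' Construct a movie stack
#'
#' @param frames array ny x nx x T (or a matrix for a single frame) of
#'   non-negative intensities; rows index y, columns x.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param channel optional channel label.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval, channel = "ch1") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stop_arg(length(dim(frames)) == 3L && dim(frames)[3] >= 1,
           "frames must be an ny x nx x T array with T >= 1")
  stop_arg(pixel_size > 0, "pixel_size must be > 0")
  stop_arg(frame_interval > 0, "frame_interval must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d x %d px, %d frames, %g um/px, %g s/frame\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}
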