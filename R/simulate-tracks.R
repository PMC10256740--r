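#' Simulate granule trajectories under a motion model
#'
#' Generates `n_tracks` trajectories of `acq$n_frames` positions at
#' `acq$frame_interval` spacing. Start positions are uniform over the field
#' of view (or its centre with `start = "center"`). With
#' `boundary = "reflect"` (default) positions are folded back at the field
#' edges so tracks never leave the frame; `boundary = "none"` leaves runs
#' unbounded, which is useful when exact excursions matter and no rendering
#' is intended.
#'
#' Ground-truth parameters (per-track speed, heading, model parameters) are
#' stored in the `truth` element so estimators can be validated by parameter
#' recovery.
#'
#' @param model a [motion_model()].
#' @param acq an [acquisition_spec()]; its `seed` makes the simulation fully
#'   reproducible.
#' @param n_tracks number of tracks (> 0).
#' @param boundary `"reflect"` or `"none"`.
#' @param start `"uniform"`, `"center"`, or `"grid"` (an evenly spaced
#'   lattice, guaranteeing initial separation).
#' @param start_margin inset of uniform start positions from the field
#'   edges, um (keeps rendered spots resolvable by detectors that cannot
#'   place maxima on the image border).
#' @return a `track_set`: list with `tracks` (data.frame `track_id`, `frame`,
#'   `x_um`, `y_um`), `truth` (per-track generative parameters),
#'   `frame_interval`, `pixel_size`, and `fov` (um).
#' @export
simulate_tracks <- function(model, acq, n_tracks,
                            boundary = c("reflect", "none"),
                            start = c("uniform", "center", "grid"),
                            start_margin = 0) {
  stopifnot(inherits(model, "motion_model"), inherits(acq, "acquisition_spec"))
  boundary <- match.arg(boundary)
  start <- match.arg(start)
  stop_arg(is.numeric(n_tracks) && length(n_tracks) == 1L && n_tracks >= 1,
           "n_tracks must be a positive count")
  n_tracks <- as.integer(n_tracks)
  fov <- fov_um(acq)
  dt <- acq$frame_interval
  nf <- acq$n_frames

  with_seed(acq$seed, {
    speeds <- headings <- rep(NA_real_, n_tracks)
    if (model$kind %in% c("directed", "switching")) {
      speeds <- rtruncnorm_pos(n_tracks, max(model$v, 1e-12), model$v_sd)
      if (model$v == 0) speeds <- rep(0, n_tracks)
      headings <- if (is.na(model$heading))
        stats::runif(n_tracks, 0, 2 * pi) else rep(model$heading, n_tracks)
    }
    stop_arg(start_margin >= 0 && 2 * start_margin < min(fov),
             "start_margin must be non-negative and smaller than half the field")
    xs <- switch(start,
      uniform = cbind(stats::runif(n_tracks, start_margin, fov["x"] - start_margin),
                      stats::runif(n_tracks, start_margin, fov["y"] - start_margin)),
      center  = cbind(rep(fov["x"] / 2, n_tracks), rep(fov["y"] / 2, n_tracks)),
      grid = {
        # evenly spaced lattice inset by the margin: guarantees spots start
        # well separated (fixtures for detection-fidelity checks)
        k <- ceiling(sqrt(n_tracks))
        gx <- seq(start_margin, fov["x"] - start_margin, length.out = k)
        gy <- seq(start_margin, fov["y"] - start_margin, length.out = k)
        g <- as.matrix(expand.grid(gx, gy))[seq_len(n_tracks), , drop = FALSE]
        unname(g)
      })

    per_track <- lapply(seq_len(n_tracks), function(i) {
      p0 <- xs[i, ]
      pos <- switch(model$kind,
        stationary = matrix(rep(p0, each = nf), ncol = 2),
        brownian = {
          sd <- sqrt(2 * model$D * dt)
          cbind(p0[1] + cumsum(c(0, stats::rnorm(nf - 1, 0, sd))),
                p0[2] + cumsum(c(0, stats::rnorm(nf - 1, 0, sd))))
        },
        directed = {
          step <- speeds[i] * dt
          k <- 0:(nf - 1)
          cbind(p0[1] + k * step * cos(headings[i]),
                p0[2] + k * step * sin(headings[i]))
        },
        confined = simulate_confined(p0, model$D, model$corral_radius, nf, dt),
        switching = simulate_switching(p0, model, speeds[i], headings[i], nf, dt))
      if (boundary == "reflect") {
        pos[, 1] <- reflect_into(pos[, 1], fov["x"])
        pos[, 2] <- reflect_into(pos[, 2], fov["y"])
      }
      data.frame(track_id = i, frame = 0:(nf - 1),
                 x_um = pos[, 1], y_um = pos[, 2])
    })

    truth <- data.frame(track_id = seq_len(n_tracks), kind = model$kind,
                        D = if (is.null(model$D)) NA_real_ else model$D,
                        speed = speeds, heading = headings,
                        corral_radius = if (is.null(model$corral_radius))
                          NA_real_ else model$corral_radius)
    track_set(do.call(rbind, per_track), frame_interval = dt,
              pixel_size = acq$pixel_size, fov = fov, truth = truth)
  })
}

# Brownian motion reflected into a disc of given radius about the start.
simulate_confined <- function(p0, D, radius, nf, dt) {
  sd <- sqrt(2 * D * dt)
  pos <- matrix(0, nf, 2)
  pos[1, ] <- p0
  for (t in seq_len(nf - 1)) {
    p <- pos[t, ] + stats::rnorm(2, 0, sd)
    d <- sqrt(sum((p - p0)^2))
    if (d > radius) {
      # radial reflection across the corral boundary
      d_ref <- max(2 * radius - d, 0)
      p <- p0 + (p - p0) / d * d_ref
    }
    pos[t + 1, ] <- p
  }
  pos
}

# Two-state motion: state 1 diffusive (D), state 2 directed (speed, heading).
# Frame-wise transitions with probability rate * dt.
simulate_switching <- function(p0, model, speed, heading, nf, dt) {
  p_out <- pmin(model$switch_rates * dt, 1)
  pos <- matrix(0, nf, 2)
  pos[1, ] <- p0
  state <- 1L
  sd <- sqrt(2 * model$D * dt)
  dir_step <- speed * dt * c(cos(heading), sin(heading))
  for (t in seq_len(nf - 1)) {
    step <- if (state == 1L) stats::rnorm(2, 0, sd) else dir_step
    pos[t + 1, ] <- pos[t, ] + step
    if (stats::runif(1) < p_out[state]) state <- 3L - state
  }
  pos
}

#' Construct a track set from a tracks table
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval seconds between consecutive frames.
#' @param pixel_size um per pixel (optional, for rendering).
#' @param fov field-of-view extent in um (optional).
#' @param truth optional per-track ground-truth table.
#' @return an object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval, pixel_size = NA_real_,
                      fov = NULL, truth = NULL) {
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  stop_arg(length(miss) == 0,
           paste("tracks table missing column(s):", paste(miss, collapse = ", ")))
  stop_arg(frame_interval > 0, "frame_interval must be > 0")
  ord <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, truth = truth,
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 fov = fov),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d points, frame interval %g s\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              x$frame_interval))
  invisible(x)
}

# Split a track_set into a named list of per-track data.frames.
split_tracks <- function(ts) split(ts$tracks, ts$tracks$track_id)
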