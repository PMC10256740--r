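# Kymograph construction, processive-run calling, and two-channel
# co-transport fractions for motor-driven granule transport.

#' Line ROI along a neurite
#'
#' @param vertices two-column matrix of polyline vertices, um.
#' @param width number of parallel lines (pixels) averaged perpendicular to
#'   the polyline.
#' @return an object of class `line_roi`.
#' @export
line_roi <- function(vertices, width = 1) {
  vertices <- as.matrix(vertices)
  stop_arg(ncol(vertices) == 2 && nrow(vertices) >= 2,
           "line ROI needs >= 2 two-dimensional vertices")
  seg <- diff(vertices)
  len <- sum(sqrt(rowSums(seg^2)))
  stop_arg(len > 0, "line ROI must have positive length")
  stop_arg(width >= 1, "width must be >= 1")
  structure(list(vertices = vertices, width = as.integer(width), length = len),
            class = "line_roi")
}

# Points along a polyline every `step` um (including both ends' range),
# together with unit normals for width averaging.
polyline_samples <- function(vertices, step) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(seg))
  frac <- (s - cum[idx]) / seg_len[idx]
  pts <- vertices[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- seg[idx, , drop = FALSE] / seg_len[idx]
  list(s = s, points = pts, normals = cbind(-tang[, 2], tang[, 1]))
}

bilinear_sample <- function(frame, x_px, y_px) {
  nr <- nrow(frame); nc <- ncol(frame)
  x0 <- floor(x_px); y0 <- floor(y_px)
  fx <- x_px - x0; fy <- y_px - y0
  cl <- function(i, n) pmin(pmax(i, 0L), n - 1L)
  g <- function(yy, xx) frame[cbind(cl(yy, nr) + 1L, cl(xx, nc) + 1L)]
  (1 - fy) * ((1 - fx) * g(y0, x0) + fx * g(y0, x0 + 1)) +
    fy * ((1 - fx) * g(y0 + 1, x0) + fx * g(y0 + 1, x0 + 1))
}

#' Build a kymograph along a line ROI
#'
#' For every frame the movie is sampled by bilinear interpolation at
#' `position_step` intervals along the polyline (default: one pixel, the
#' behaviour of image-reslicing tools) and averaged across `roi$width`
#' parallel offsets perpendicular to the line. Rows are positions along the
#' line, columns are frames.
#'
#' @param movie a `movie_stack`.
#' @param roi a [line_roi()].
#' @param position_step sampling step along the line, um; defaults to the
#'   movie pixel size.
#' @return a `kymograph`: list with `matrix`, `position_step`,
#'   `frame_interval`, `positions_um`.
#' @export
make_kymograph <- function(movie, roi, position_step = NULL) {
  stopifnot(inherits(movie, "movie_stack"), inherits(roi, "line_roi"))
  if (is.null(position_step)) position_step <- movie$pixel_size
  stop_arg(position_step > 0, "position_step must be > 0")
  d <- dim(movie$frames)
  fov_x <- (d[2] - 1) * movie$pixel_size
  fov_y <- (d[1] - 1) * movie$pixel_size
  v <- roi$vertices
  if (any(v[, 1] < 0 | v[, 1] > fov_x | v[, 2] < 0 | v[, 2] > fov_y))
    stop("line ROI falls outside the field of view", call. = FALSE)
  ps <- polyline_samples(v, position_step)
  offs <- (seq_len(roi$width) - (roi$width + 1) / 2) * movie$pixel_size
  nt <- d[3]
  kymo <- matrix(0, nrow = length(ps$s), ncol = nt)
  for (t in seq_len(nt)) {
    fr <- movie$frames[, , t]
    acc <- 0
    for (o in offs) {
      px <- (ps$points[, 1] + o * ps$normals[, 1]) / movie$pixel_size
      py <- (ps$points[, 2] + o * ps$normals[, 2]) / movie$pixel_size
      acc <- acc + bilinear_sample(fr, px, py)
    }
    kymo[, t] <- acc / length(offs)
  }
  structure(list(matrix = kymo, position_step = position_step,
                 frame_interval = movie$frame_interval, positions_um = ps$s),
            class = "kymograph")
}

#' Distance and velocity from a kymograph line
#'
#' A manually traced line on a kymograph from (position, frame) `p0` to `p1`
#' gives distance = |delta position| and velocity = distance over elapsed
#' time, reproducing the length-and-angle readout of kymograph tracing.
#'
#' @param p0,p1 numeric length-2: (position um, frame index).
#' @param frame_interval seconds per frame (kymograph column spacing).
#' @return list with `distance_um`, `velocity_um_per_s`.
#' @export
run_from_kymo_line <- function(p0, p1, frame_interval) {
  stop_arg(length(p0) == 2 && length(p1) == 2, "p0 and p1 must be (position, frame)")
  stop_arg(p1[2] > p0[2], "p1 must be at a later frame than p0")
  stop_arg(frame_interval > 0, "frame_interval must be > 0")
  dist <- abs(p1[1] - p0[1])
  list(distance_um = dist,
       velocity_um_per_s = dist / ((p1[2] - p0[2]) * frame_interval))
}

# Project track positions onto the first principal component of the track.
principal_axis_projection <- function(tr) {
  xy <- cbind(tr$x_um, tr$y_um)
  xyc <- sweep(xy, 2, colMeans(xy))
  sv <- svd(xyc, nu = 0, nv = 1)
  as.numeric(xyc %*% sv$v[, 1])
}

#' Call processive runs along a track
#'
#' Positions are projected onto the track's first principal component (in
#' neurites, motion is effectively one-dimensional along the process).
#' Maximal monotone excursions of the projected coordinate whose net
#' displacement is at least `min_run` are reported; the default 2 um
#' threshold matches the definition of long processive movements.
#'
#' @param track data.frame (`frame`, `x_um`, `y_um`) or single-track
#'   `track_set`.
#' @param min_run minimum net displacement of a run, um (> 0).
#' @return data.frame of run events: `start_frame`, `end_frame`,
#'   `displacement_um`, `direction` (+1/-1 along the principal axis).
#' @export
call_processive_runs <- function(track, min_run = 2) {
  stop_arg(min_run > 0, "min_run must be > 0")
  tr <- as_track_df(track)
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      displacement_um = numeric(0), direction = numeric(0))
  if (nrow(tr) < 2) return(empty)
  proj <- principal_axis_projection(tr)
  d <- diff(proj)
  if (all(d == 0)) return(empty)
  sgn <- sign(d)
  # zero steps continue the current run; leading zeros take the first sign
  nz <- which(sgn != 0)
  sgn[seq_len(nz[1] - 1)] <- sgn[nz[1]]
  for (i in seq_along(sgn)[-1]) if (sgn[i] == 0) sgn[i] <- sgn[i - 1]
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  runs <- data.frame(start_frame = tr$frame[starts],
                     end_frame = tr$frame[ends + 1],
                     displacement_um = abs(proj[ends + 1] - proj[starts]),
                     direction = r$values)
  runs[runs$displacement_um >= min_run, , drop = FALSE]
}

#' Fraction of reference tracks co-transported with a partner channel
#'
#' A reference track with at least one processive run counts as
#' co-transported if, for some run, a single partner track lies within
#' `max_gap` of the reference position in at least `min_overlap_fraction`
#' of the run's frames. The fraction is over reference tracks that have at
#' least one run. Both channels must share a time base.
#'
#' @param reference,partner `track_set` objects from the two channels.
#' @param max_gap maximum instantaneous separation, um.
#' @param min_overlap_fraction minimum fraction of run frames within
#'   `max_gap`.
#' @param min_run processive-run threshold passed to
#'   [call_processive_runs()], um.
#' @return list with `fraction`, `n_reference` (tracks with runs),
#'   `n_cotransported`, and a per-track logical table.
#' @export
cotransport_fraction <- function(reference, partner, max_gap = 0.5,
                                 min_overlap_fraction = 0.5, min_run = 2) {
  stopifnot(inherits(reference, "track_set"), inherits(partner, "track_set"))
  if (abs(reference$frame_interval - partner$frame_interval) > 1e-12)
    stop("reference and partner channels must share a time base", call. = FALSE)
  ref_tracks <- split_tracks(reference)
  stop_arg(length(ref_tracks) > 0, "reference track set is empty")
  par_tracks <- split_tracks(partner)
  results <- lapply(ref_tracks, function(tr) {
    runs <- call_processive_runs(tr, min_run)
    if (nrow(runs) == 0) return(c(has_run = FALSE, co = FALSE))
    co <- FALSE
    for (k in seq_len(nrow(runs))) {
      fr <- tr$frame >= runs$start_frame[k] & tr$frame <= runs$end_frame[k]
      seg <- tr[fr, , drop = FALSE]
      for (pt in par_tracks) {
        m <- match(seg$frame, pt$frame)
        ok <- !is.na(m)
        if (!any(ok)) next
        gap <- sqrt((seg$x_um[ok] - pt$x_um[m[ok]])^2 +
                    (seg$y_um[ok] - pt$y_um[m[ok]])^2)
        if (sum(gap <= max_gap) >= min_overlap_fraction * nrow(seg)) {
          co <- TRUE
          break
        }
      }
      if (co) break
    }
    c(has_run = TRUE, co = co)
  })
  has_run <- vapply(results, function(x) unname(x["has_run"]), logical(1))
  co <- vapply(results, function(x) unname(x["co"]), logical(1))
  n_ref <- sum(has_run)
  frac <- if (n_ref > 0) sum(co[has_run]) / n_ref else NA_real_
  list(fraction = frac, n_reference = n_ref, n_cotransported = sum(co[has_run]),
       per_track = data.frame(track_id = as.integer(names(ref_tracks)),
                              has_run = has_run, cotransported = co))
}
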