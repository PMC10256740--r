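# Spot detection and linking: movie -> filtered particle tracks.
# Pipeline order follows the granule-dynamics protocol: rolling-ball
# background correction, Laplacian-of-Gaussian detection at the granule
# scale (~0.5 um diameter), greedy mutual-nearest-neighbour linking, and a
# minimum track-length filter (> 20 frames).

# Replicate-pad a matrix by (kr, kc) on each side.
pad_replicate <- function(m, kr, kc) {
  ri <- c(rep(1L, kr), seq_len(nrow(m)), rep(nrow(m), kr))
  ci <- c(rep(1L, kc), seq_len(ncol(m)), rep(ncol(m), kc))
  m[ri, ci, drop = FALSE]
}

# 2-D convolution/correlation with replicate padding (kernel assumed
# symmetric where it matters). Shift-and-accumulate over kernel support.
conv2_replicate <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  pad <- pad_replicate(m, kr, kc)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      k <- kernel[i, j]
      if (k != 0)
        out <- out + k * pad[i:(i + nrow(m) - 1L), j:(j + ncol(m) - 1L)]
    }
  }
  out
}

# Offsets of a flat disc structuring element of given radius (pixels).
disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# Grayscale erosion/dilation with a flat disc, replicate padding.
morph_disc <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  off <- disc_offsets(radius)
  r <- as.integer(radius)
  pad <- pad_replicate(m, r, r)
  acc <- NULL
  for (k in seq_len(nrow(off))) {
    sub <- pad[(1 + r + off$dy[k]):(r + off$dy[k] + nrow(m)),
               (1 + r + off$dx[k]):(r + off$dx[k] + ncol(m)), drop = FALSE]
    acc <- if (is.null(acc)) sub
           else if (op == "erode") pmin(acc, sub) else pmax(acc, sub)
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a frame by grayscale opening with a
#' disc structuring element of the given radius (the flat-disc form of the
#' classic rolling-ball filter, adequate at the small radii used for
#' diffraction-limited spots) and subtracts it. Output is clamped at zero.
#' The default radius of 3 pixels matches the granule-dynamics protocol.
#'
#' @param frame numeric matrix of intensities.
#' @param radius structuring-element radius in pixels (>= 1).
#' @return matrix of the same size, non-negative.
#' @export
rolling_ball_subtract <- function(frame, radius = 3) {
  stop_arg(is.matrix(frame) && is.numeric(frame), "frame must be a numeric matrix")
  stop_arg(radius >= 1, "radius must be >= 1")
  stop_arg(radius < min(dim(frame)),
           "rolling-ball radius must be smaller than the image dimensions")
  bg <- morph_disc(morph_disc(frame, radius, "erode"), radius, "dilate")
  pmax(frame - bg, 0)
}

# Scale-normalized negated Laplacian-of-Gaussian kernel; blobs of the
# matched scale give positive peaks.
log_kernel <- function(sigma_px) {
  half <- max(2L, ceiling(4 * sigma_px))
  x <- -half:half
  g <- expand.grid(y = x, x = x)
  r2 <- g$x^2 + g$y^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 *
    exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k)  # zero response to constant images
  matrix(k, nrow = length(x))
}

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) == 0) return(Inf)
  h <- hist(x, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# Automatic quality cutoff: Otsu on the local-maximum responses, applied
# only when the split is genuinely bimodal (noise floor well below the
# signal class). In noise-free movies every local maximum is a true spot
# and thresholding would discard real detections.
auto_quality_threshold <- function(q) {
  t <- otsu_threshold(q)
  lo <- q[q < t]
  hi <- q[q >= t]
  if (length(lo) == 0 || length(hi) == 0) return(-Inf)
  if (mean(lo) > 0.5 * mean(hi)) return(-Inf)  # unimodal: keep all
  t
}

#' Detect diffraction-limited spots in a movie
#'
#' Per frame: optional rolling-ball background correction, a
#' scale-normalized Laplacian-of-Gaussian filter at sigma =
#' diameter / (2 * sqrt(2)), strict 8-neighbourhood local-maximum selection,
#' sub-pixel refinement by a 1-D quadratic fit per axis, and a quality
#' cutoff. When `quality_threshold` is `NULL` an Otsu threshold on the
#' movie-wide distribution of local-maximum responses is used.
#'
#' @param movie a `movie_stack`.
#' @param diameter expected spot diameter, um (default 0.5, the typical RNP
#'   granule size).
#' @param quality_threshold detector-response cutoff; `NULL` for automatic.
#' @param subtract_background apply [rolling_ball_subtract()] first.
#' @param rolling_ball_radius radius for the background correction, pixels.
#' @return data.frame with columns `frame` (0-based), `x_um`, `y_um`,
#'   `quality`.
#' @export
detect_spots <- function(movie, diameter = 0.5, quality_threshold = NULL,
                         subtract_background = TRUE, rolling_ball_radius = 3) {
  stopifnot(inherits(movie, "movie_stack"))
  stop_arg(diameter > 0, "diameter must be > 0")
  stop_arg(diameter >= movie$pixel_size,
           "spot diameter must be at least one pixel")
  sigma_px <- diameter / (2 * sqrt(2)) / movie$pixel_size
  kern <- log_kernel(sigma_px)
  nt <- dim(movie$frames)[3]
  cand <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- movie$frames[, , t]
    if (subtract_background) fr <- rolling_ball_subtract(fr, rolling_ball_radius)
    resp <- conv2_replicate(fr, kern)
    cand[[t]] <- local_maxima(resp, frame0 = t - 1L)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), quality = numeric(0)))
  }
  thr <- if (is.null(quality_threshold)) auto_quality_threshold(cand$quality)
         else quality_threshold
  cand <- cand[cand$quality >= thr, , drop = FALSE]
  data.frame(frame = cand$frame,
             x_um = cand$x_px * movie$pixel_size,
             y_um = cand$y_px * movie$pixel_size,
             quality = cand$quality)
}

# Strict local maxima of a response matrix, with quadratic sub-pixel
# refinement. Returns 0-based pixel coordinates.
local_maxima <- function(resp, frame0) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) {
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), quality = numeric(0)))
  }
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > resp[1:(nr - 2), 2:(nc - 1)] &
            core > resp[3:nr,       2:(nc - 1)] &
            core > resp[2:(nr - 1), 1:(nc - 2)] &
            core > resp[2:(nr - 1), 3:nc] &
            core > resp[1:(nr - 2), 1:(nc - 2)] &
            core > resp[1:(nr - 2), 3:nc] &
            core > resp[3:nr,       1:(nc - 2)] &
            core > resp[3:nr,       3:nc] &
            core > 0
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), quality = numeric(0)))
  }
  ri <- idx[, 1] + 1L  # back to full-matrix indices
  ci <- idx[, 2] + 1L
  q <- resp[cbind(ri, ci)]
  # quadratic refinement per axis, offset clamped to +/- 0.5 px
  dy <- refine_offset(resp[cbind(ri - 1L, ci)], q, resp[cbind(ri + 1L, ci)])
  dx <- refine_offset(resp[cbind(ri, ci - 1L)], q, resp[cbind(ri, ci + 1L)])
  data.frame(frame = frame0, x_px = (ci - 1L) + dx, y_px = (ri - 1L) + dy,
             quality = q)
}

refine_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm - fp) / den, 0)
  pmin(pmax(off, -0.5), 0.5)
}

#' Link detected spots into tracks
#'
#' Greedy frame-to-frame linking: for each consecutive frame pair, spots
#' that are mutually nearest neighbours and closer than `max_displacement`
#' are joined; unmatched spots start new tracks. There is no gap closing,
#' splitting, or merging, so a spot missing in one frame splits its track.
#' Determinism: spots are sorted by (frame, y, x) and distance ties are
#' broken by the lower spot index.
#'
#' @param spots data.frame with `frame`, `x_um`, `y_um` (extra columns kept).
#' @param max_displacement maximum allowed displacement per frame, um.
#' @param frame_interval seconds between frames (stored on the result).
#' @return a `track_set`; tracks of a single point are kept and removed by
#'   [filter_tracks()].
#' @export
link_spots <- function(spots, max_displacement, frame_interval = 0.1) {
  stop_arg(max_displacement > 0, "max_displacement must be > 0")
  need <- c("frame", "x_um", "y_um")
  miss <- setdiff(need, names(spots))
  stop_arg(length(miss) == 0,
           paste("spots table missing column(s):", paste(miss, collapse = ", ")))
  spots <- spots[order(spots$frame, spots$y_um, spots$x_um), , drop = FALSE]
  rownames(spots) <- NULL
  n <- nrow(spots)
  if (n == 0) {
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x_um = numeric(0), y_um = numeric(0)),
                     frame_interval = frame_interval))
  }
  track_of <- integer(n)
  next_id <- 1L
  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(n), spots$frame)
  # seed tracks in the first frame
  first <- idx_by_frame[[as.character(frames[1])]]
  track_of[first] <- seq_along(first)
  next_id <- length(first) + 1L
  for (f in seq_along(frames)[-1]) {
    cur <- idx_by_frame[[as.character(frames[f])]]
    linked <- rep(FALSE, length(cur))
    if (frames[f] - frames[f - 1] == 1) {  # consecutive frames only
      prev <- idx_by_frame[[as.character(frames[f - 1])]]
      if (length(prev) > 0 && length(cur) > 0) {
        dmat <- outer(spots$x_um[prev], spots$x_um[cur], "-")^2 +
                outer(spots$y_um[prev], spots$y_um[cur], "-")^2
        dmat <- sqrt(dmat)
        # mutual nearest neighbours within max_displacement;
        # which.min returns the first (lowest-index) minimiser => ties
        # break toward the lower index after the (frame, y, x) sort.
        best_for_prev <- apply(dmat, 1, which.min)
        best_for_cur <- apply(dmat, 2, which.min)
        for (j in seq_along(cur)) {
          i <- best_for_cur[j]
          if (best_for_prev[i] == j && dmat[i, j] <= max_displacement) {
            track_of[cur[j]] <- track_of[prev[i]]
            linked[j] <- TRUE
          }
        }
      }
    }
    for (j in which(!linked)) {
      track_of[cur[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- data.frame(track_id = track_of, frame = spots$frame,
                    x_um = spots$x_um, y_um = spots$y_um)
  # renumber tracks in order of first appearance
  out$track_id <- match(out$track_id, unique(out$track_id[order(out$frame)]))
  track_set(out, frame_interval = frame_interval)
}

#' Filter tracks by minimum length
#'
#' Retains tracks with at least `min_frames` points. The default of 21
#' implements the "> 20 frames (2 s)" track-length threshold of the granule
#' dynamics protocol at 10 frames/s. Idempotent.
#'
#' @param tracks a `track_set`.
#' @param min_frames minimum number of points (>= 2).
#' @return a `track_set` containing only the retained tracks.
#' @export
filter_tracks <- function(tracks, min_frames = 21) {
  stopifnot(inherits(tracks, "track_set"))
  stop_arg(min_frames >= 2, "min_frames must be >= 2")
  tb <- tracks$tracks
  keep_ids <- names(which(table(tb$track_id) >= min_frames))
  tb <- tb[tb$track_id %in% keep_ids, , drop = FALSE]
  truth <- tracks$truth
  if (!is.null(truth)) truth <- truth[truth$track_id %in% keep_ids, , drop = FALSE]
  track_set(tb, frame_interval = tracks$frame_interval,
            pixel_size = tracks$pixel_size, fov = tracks$fov, truth = truth)
}
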