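# Per-track dynamics: MSD, diffusion coefficient, maximum excursion,
# velocity; per-cell and ensemble summaries; group comparison.

as_track_df <- function(track) {
  if (inherits(track, "track_set")) {
    ids <- unique(track$tracks$track_id)
    stop_arg(length(ids) == 1L,
             "expected a single track; use summarize_dynamics() for a set")
    return(track$tracks)
  }
  stop_arg(all(c("frame", "x_um", "y_um") %in% names(track)),
           "track must have columns frame, x_um, y_um")
  track[order(track$frame), , drop = FALSE]
}

#' Mean squared displacement of a track
#'
#' MSD at lag k is the mean over all ordered pairs of points k frames apart
#' (overlapping windows) of the squared Euclidean displacement, for
#' k = 1...max_lag. The default `max_lag = 7` follows the granule-dynamics
#' protocol ("up to lag time 7").
#'
#' @param track data.frame (`frame`, `x_um`, `y_um`) or a single-track
#'   `track_set`.
#' @param max_lag largest lag in frames.
#' @param frame_interval seconds per frame (taken from the `track_set` when
#'   available).
#' @return an `msd_profile` data.frame with columns `lag`, `tau_s`, `msd`,
#'   `n_pairs`.
#' @export
msd <- function(track, max_lag = 7, frame_interval = NULL) {
  if (inherits(track, "track_set") && is.null(frame_interval))
    frame_interval <- track$frame_interval
  tr <- as_track_df(track)
  stop_arg(!is.null(frame_interval) && frame_interval > 0,
           "frame_interval must be supplied (seconds per frame)")
  n <- nrow(tr)
  if (n <= max_lag)
    stop(sprintf("track too short for max_lag %d: need > %d points, got %d",
                 max_lag, max_lag, n), call. = FALSE)
  # index positions by frame so missing frames contribute no pairs
  f0 <- tr$frame - min(tr$frame)
  pos <- matrix(NA_real_, max(f0) + 1L, 2)
  pos[f0 + 1L, ] <- cbind(tr$x_um, tr$y_um)
  out <- lapply(seq_len(max_lag), function(k) {
    if (nrow(pos) <= k) return(data.frame(lag = k, tau_s = k * frame_interval,
                                          msd = NA_real_, n_pairs = 0L))
    d <- (pos[-seq_len(k), 1] - pos[seq_len(nrow(pos) - k), 1])^2 +
         (pos[-seq_len(k), 2] - pos[seq_len(nrow(pos) - k), 2])^2
    d <- d[is.finite(d)]
    data.frame(lag = k, tau_s = k * frame_interval,
               msd = if (length(d)) mean(d) else NA_real_,
               n_pairs = length(d))
  })
  out <- do.call(rbind, out)
  class(out) <- c("msd_profile", "data.frame")
  out
}

#' Diffusion coefficient from an MSD profile
#'
#' Fits an ordinary-least-squares line (free intercept, which absorbs static
#' localization error; the intercept is discarded) to MSD versus lag time.
#' Under the default `"slope4"` convention the 2-D Brownian relation
#' MSD = 4 D tau gives D = slope / 4; the `"slope"` convention reports the
#' raw slope itself. A negative fitted slope is clamped to zero and flagged
#' via the `"clamped"` attribute.
#'
#' @param profile an `msd_profile` (or data.frame with `tau_s` and `msd`).
#' @param convention `"slope4"` (default) or `"slope"`.
#' @return diffusion coefficient in um^2/s (attribute `clamped` is TRUE when
#'   the fitted slope was negative).
#' @export
diffusion_coefficient <- function(profile, convention = c("slope4", "slope")) {
  convention <- match.arg(convention)
  stop_arg(all(c("tau_s", "msd") %in% names(profile)),
           "profile must have columns tau_s and msd")
  ok <- is.finite(profile$msd) & is.finite(profile$tau_s)
  tau <- profile$tau_s[ok]
  y <- profile$msd[ok]
  stop_arg(length(tau) >= 2, "need at least 2 lags to fit a slope")
  if (diff(range(tau)) == 0) stop("all lag times are equal", call. = FALSE)
  slope <- sum((tau - mean(tau)) * (y - mean(y))) / sum((tau - mean(tau))^2)
  d <- if (convention == "slope4") slope / 4 else slope
  clamped <- d < 0
  if (clamped) d <- 0
  structure(d, clamped = clamped)
}

#' Maximum distance from track start
#'
#' The largest Euclidean distance between the first point of the track and
#' any later point ("the furthest point away from the track start").
#'
#' @inheritParams msd
#' @return distance in um.
#' @export
max_distance <- function(track) {
  tr <- as_track_df(track)
  stop_arg(nrow(tr) >= 2, "track needs at least 2 points")
  max(sqrt((tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2))
}

#' Mean track velocity
#'
#' Total path length (sum of consecutive-point Euclidean distances) divided
#' by elapsed time. Always at least the net displacement rate.
#'
#' @inheritParams msd
#' @return velocity in um/s.
#' @export
track_velocity <- function(track, frame_interval = NULL) {
  if (inherits(track, "track_set") && is.null(frame_interval))
    frame_interval <- track$frame_interval
  tr <- as_track_df(track)
  stop_arg(!is.null(frame_interval) && frame_interval > 0,
           "frame_interval must be supplied (seconds per frame)")
  stop_arg(nrow(tr) >= 2, "track needs at least 2 points")
  elapsed <- (tr$frame[nrow(tr)] - tr$frame[1]) * frame_interval
  stop_arg(elapsed > 0, "elapsed time must be > 0")
  path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
  path / elapsed
}

#' Per-track, per-cell and ensemble dynamics summary
#'
#' Computes D (MSD slope / 4 by default), log10 D, maximum distance, and
#' velocity per track; medians of each per cell; and ensemble (all-track)
#' medians. log10 D is reported only for D > 0; the number of zero/clamped
#' estimates is returned separately.
#'
#' @param tracks a `track_set`.
#' @param cell_map named vector or data.frame (`track_id`, `cell_id`)
#'   assigning every track to a cell; `NULL` puts all tracks in one cell.
#' @param max_lag MSD lags used for the diffusion fit.
#' @param convention diffusion convention, see [diffusion_coefficient()].
#' @return a `dynamics_summary` list: `per_track`, `per_cell`, `ensemble`,
#'   `n_zero_D`.
#' @export
summarize_dynamics <- function(tracks, cell_map = NULL, max_lag = 7,
                               convention = "slope4") {
  stopifnot(inherits(tracks, "track_set"))
  trs <- split_tracks(tracks)
  ids <- as.integer(names(trs))
  if (is.null(cell_map)) {
    cells <- setNames(rep(1L, length(ids)), ids)
  } else if (is.data.frame(cell_map)) {
    cells <- setNames(cell_map$cell_id, cell_map$track_id)
  } else cells <- cell_map
  unmapped <- setdiff(as.character(ids), names(cells))
  if (length(unmapped) > 0)
    stop("track(s) not mapped to a cell: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  dt <- tracks$frame_interval
  per <- do.call(rbind, lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    D <- as.numeric(diffusion_coefficient(msd(tr, max_lag, dt), convention))
    data.frame(track_id = ids[i], cell_id = cells[[as.character(ids[i])]],
               D_um2_per_s = D,
               log10_D = if (D > 0) log10(D) else NA_real_,
               d_max_um = max_distance(tr),
               velocity_um_per_s = track_velocity(tr, dt))
  }))
  med <- function(x) stats::median(x, na.rm = TRUE)
  per_cell <- do.call(rbind, lapply(split(per, per$cell_id), function(g) {
    data.frame(cell_id = g$cell_id[1], n_tracks = nrow(g),
               D_um2_per_s = med(g$D_um2_per_s), log10_D = med(g$log10_D),
               d_max_um = med(g$d_max_um),
               velocity_um_per_s = med(g$velocity_um_per_s))
  }))
  rownames(per_cell) <- NULL
  ensemble <- data.frame(n_tracks = nrow(per),
                         D_um2_per_s = med(per$D_um2_per_s),
                         log10_D = med(per$log10_D),
                         d_max_um = med(per$d_max_um),
                         velocity_um_per_s = med(per$velocity_um_per_s))
  structure(list(per_track = per, per_cell = per_cell, ensemble = ensemble,
                 n_zero_D = sum(per$D_um2_per_s == 0)),
            class = "dynamics_summary")
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact permutation enumeration (all assignments of the pooled values to
#' the two groups, correct under ties) when n_a + n_b <= 12; otherwise the
#' normal approximation with tie correction and no continuity correction.
#' The two-tailed exact p-value is the permutation probability of a U at
#' least as far from its null mean as observed.
#'
#' @param a,b numeric vectors of per-cell (or per-track) statistics.
#' @return list with `U` (for group `a`), `p`, `method`.
#' @export
compare_groups <- function(a, b) {
  stop_arg(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  stop_arg(all(is.finite(a)) && all(is.finite(b)), "groups must be finite")
  na <- length(a); nb <- length(b)
  u_stat <- function(ra_sum) ra_sum - na * (na + 1) / 2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- u_stat(sum(r[seq_len(na)]))
  mu <- na * nb / 2
  if (na + nb <= 12) {
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    z <- if (sigma > 0) (U - mu) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method)
}
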