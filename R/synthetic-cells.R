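# Synthetic fixtures for recruitment scoring and FISH spot statistics:
# cell images with controlled centrosome enrichment, and neurite fields
# with distance-distributed spots.

#' Binary disc mask
#'
#' @param nx,ny mask size, pixels.
#' @param center (x, y) centre in pixels (0-based pixel coordinates).
#' @param radius disc radius, pixels.
#' @return logical matrix ny x nx.
#' @export
disc_mask <- function(nx, ny, center, radius) {
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Synthetic cell image with a prescribed centrosome enrichment
#'
#' Builds a noise-free image that is exactly consistent with a requested
#' log2 centrosome enrichment: intensity is uniform at `a` in the cell
#' outside the centrosome and `b` inside it, with `b` solved so that the
#' centrosome mean equals `2^enrichment` times the whole-cell mean (cell
#' mean includes centrosome pixels). Background outside the cell is zero.
#' Optional Poisson or Gaussian noise can be layered on top for robustness
#' studies; the exactness guarantee holds only for `noise = "none"`.
#'
#' @param cell_mask,centrosome_mask binary masks; the centrosome must be a
#'   non-empty subset of the cell.
#' @param enrichment target log2 enrichment E.
#' @param base_intensity intensity `a` of the cell body (photons).
#' @param noise `"none"`, `"poisson"` or `"gaussian"`.
#' @param noise_sd SD for gaussian noise.
#' @param seed RNG seed for the noise layer.
#' @return intensity matrix of the same size as the masks.
#' @export
make_cell_image <- function(cell_mask, centrosome_mask, enrichment,
                            base_intensity = 100,
                            noise = c("none", "poisson", "gaussian"),
                            noise_sd = 2, seed = NULL) {
  noise <- match.arg(noise)
  m <- check_masks(cell_mask, centrosome_mask)
  n <- sum(m$cell)
  nc <- sum(m$centrosome)
  denom <- n - 2^enrichment * nc
  stop_arg(denom > 0,
           "enrichment too large for this centrosome/cell size ratio")
  a <- base_intensity
  b <- 2^enrichment * a * (n - nc) / denom
  img <- matrix(0, nrow(cell_mask), ncol(cell_mask))
  img[m$cell] <- a
  img[m$centrosome] <- b
  with_seed(seed, switch(noise,
    none = img,
    poisson = matrix(stats::rpois(length(img), img), nrow(img)),
    gaussian = img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))))
}

#' Convenience synthetic cell: masks plus image
#'
#' Builds a circular cell with a small off-centre centrosome disc and the
#' corresponding [make_cell_image()].
#'
#' @param enrichment target log2 enrichment.
#' @param nx,ny image size, pixels.
#' @param cell_radius,centrosome_radius disc radii, pixels.
#' @param ... passed to [make_cell_image()].
#' @return list with `image`, `cell_mask`, `centrosome_mask`.
#' @export
synthetic_cell <- function(enrichment, nx = 64, ny = 64, cell_radius = 26,
                           centrosome_radius = 3, ...) {
  ctr <- c((nx - 1) / 2, (ny - 1) / 2)
  cell <- disc_mask(nx, ny, ctr, cell_radius)
  cent <- disc_mask(nx, ny, ctr + c(cell_radius / 2, 0), centrosome_radius)
  list(image = make_cell_image(cell, cent, enrichment, ...),
       cell_mask = cell, centrosome_mask = cent)
}

#' Neurite geometry for spot-distance normalization
#'
#' @param soma_centroid (x, y) soma centre, um.
#' @param neurites list of two-column matrices, each a polyline starting at
#'   the soma end, um.
#' @param cell_id optional cell label.
#' @return an object of class `neurite_geometry` with per-neurite cumulative
#'   arclengths and total lengths.
#' @export
neurite_geometry <- function(soma_centroid, neurites, cell_id = 1L) {
  stop_arg(length(soma_centroid) == 2, "soma_centroid must be (x, y)")
  stop_arg(is.list(neurites) && length(neurites) >= 1,
           "need at least one neurite polyline")
  neurites <- lapply(neurites, as.matrix)
  lens <- vapply(neurites, function(p) {
    stop_arg(ncol(p) == 2 && nrow(p) >= 2, "neurite polylines need >= 2 vertices")
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  stop_arg(all(lens > 0), "degenerate neurite of zero length")
  structure(list(soma = as.numeric(soma_centroid), neurites = neurites,
                 lengths = lens, cell_id = cell_id),
            class = "neurite_geometry")
}

# Point at arclength fraction f along a polyline.
point_at_fraction <- function(vertices, f) {
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  target <- f * cum[length(cum)]
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  frac <- (target - cum[i]) / seg_len[i]
  vertices[i, ] + seg[i, ] * frac
}

#' Simulate a field of FISH spots along neurites
#'
#' Spots are placed at sampled arclength fractions of the cell's neurites
#' (neurite chosen with probability proportional to its length), with the
#' ground-truth fraction stored per spot. Supported fraction distributions:
#' `list(kind = "uniform")`, `list(kind = "beta", shape1 =, shape2 =)`
#' (e.g. shape2 > shape1 models depletion of distal spots), and
#' `list(kind = "point", at =)`.
#'
#' @param geometry a [neurite_geometry()].
#' @param n_spots number of spots (> 0). The default 150 matches the
#'   per-cell spot counts used for distal-distance statistics.
#' @param distance_distribution list describing the fraction distribution.
#' @param jitter_sd perpendicular jitter SD, um (0 = spots exactly on the
#'   polyline).
#' @param seed RNG seed.
#' @return data.frame `spot_id`, `cell_id`, `neurite_id`, `x_um`, `y_um`,
#'   `true_fraction`.
#' @export
simulate_neurite_field <- function(geometry, n_spots = 150,
                                   distance_distribution = list(kind = "uniform"),
                                   jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(geometry, "neurite_geometry"))
  stop_arg(is.numeric(n_spots) && n_spots >= 1, "n_spots must be a positive count")
  n_spots <- as.integer(n_spots)
  kind <- distance_distribution$kind
  stop_arg(kind %in% c("uniform", "beta", "point"),
           "distance_distribution$kind must be uniform, beta, or point")
  with_seed(seed, {
    fr <- switch(kind,
      uniform = stats::runif(n_spots),
      beta = stats::rbeta(n_spots, distance_distribution$shape1,
                          distance_distribution$shape2),
      point = rep(distance_distribution$at, n_spots))
    ni <- sample.int(length(geometry$neurites), n_spots, replace = TRUE,
                     prob = geometry$lengths)
    pts <- t(vapply(seq_len(n_spots), function(i)
      point_at_fraction(geometry$neurites[[ni[i]]], fr[i]), numeric(2)))
    if (jitter_sd > 0)
      pts <- pts + matrix(stats::rnorm(2 * n_spots, 0, jitter_sd), ncol = 2)
    data.frame(spot_id = seq_len(n_spots), cell_id = geometry$cell_id,
               neurite_id = ni, x_um = pts[, 1], y_um = pts[, 2],
               true_fraction = fr)
  })
}
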