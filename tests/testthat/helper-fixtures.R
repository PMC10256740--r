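# Fixtures shared across test files; all built in code.

# A track set with a single straight run: speed um/s along +x.
straight_track <- function(speed = 1, n_frames = 30, dt = 0.1,
                           origin = c(1, 2)) {
  track_set(data.frame(track_id = 1L, frame = 0:(n_frames - 1),
                       x_um = origin[1] + speed * dt * (0:(n_frames - 1)),
                       y_um = origin[2]),
            frame_interval = dt, pixel_size = 0.1)
}

# Noise-free rendered movie of well-separated spots on a grid.
grid_movie <- function(n_tracks = 6, D = 0.004, n_frames = 40, seed = 7,
                       nx = 128, ny = 128) {
  acq <- acquisition_spec(nx = nx, ny = ny, n_frames = n_frames,
                          noise = "none", seed = seed)
  ts <- simulate_tracks(motion_model("brownian", D = D), acq, n_tracks,
                        start = "grid", start_margin = 2)
  list(tracks = ts, movie = render_movie(ts, acq), acq = acq)
}

# Independent OLS slope oracle (closed form) for diffusion tests.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force two-tailed Mann-Whitney p by full enumeration, independent of
# compare_groups() internals.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  mu <- na * length(b) / 2
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  us <- apply(utils::combn(length(pooled), na), 2, function(ix)
    sum(r[ix]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Hypergeometric two-tailed Fisher p by enumeration over all possible
# overlaps (sum of probabilities <= observed's probability).
fisher_enum_p <- function(ov, nA, nB, N) {
  ks <- max(0, nA + nB - N):min(nA, nB)
  pr <- stats::dhyper(ks, nA, N - nA, nB)
  sum(pr[pr <= stats::dhyper(ov, nA, N - nA, nB) * (1 + 1e-7)])
}
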