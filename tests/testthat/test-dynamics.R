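# MSD, diffusion estimation, excursion, velocity, summaries, group tests.

test_that("MSD is zero for anchored tracks and quadratic for ballistic ones", {
  still <- data.frame(frame = 0:20, x_um = 2, y_um = 3)
  prof <- msd(still, frame_interval = 0.1)
  expect_equal(prof$msd, rep(0, 7))
  expect_equal(prof$n_pairs, 21 - 1:7)
  run <- data.frame(frame = 0:20, x_um = (0:20) * 1, y_um = 0)  # 1 um/s, dt 1 s
  prof2 <- msd(run, frame_interval = 1)
  expect_equal(prof2$msd, (1:7)^2, tolerance = 1e-12)
})

test_that("MSD errors on too-short tracks, naming the required length", {
  short <- data.frame(frame = 0:5, x_um = 0, y_um = 0)
  expect_error(msd(short, max_lag = 7, frame_interval = 0.1), "> 7 points")
})

test_that("mean MSD of Brownian tracks matches 4*D*k*dt within 5%", {
  acq <- acquisition_spec(nx = 400, ny = 400, n_frames = 120, noise = "none",
                          seed = 31)
  ts <- simulate_tracks(motion_model("brownian", D = 0.01), acq, 500,
                        boundary = "none", start = "center")
  profs <- lapply(split(ts$tracks, ts$tracks$track_id), msd,
                  frame_interval = 0.1)
  mean_msd <- rowMeans(vapply(profs, function(p) p$msd, numeric(7)))
  expect_equal(mean_msd, 4 * 0.01 * (1:7) * 0.1, tolerance = 0.05)
})

test_that("diffusion coefficient honours both slope conventions and clamps", {
  tau <- (1:7) * 0.1
  lin <- data.frame(tau_s = tau, msd = 4 * 0.01 * tau)
  expect_equal(as.numeric(diffusion_coefficient(lin)), 0.01, tolerance = 1e-12)
  expect_equal(as.numeric(diffusion_coefficient(lin, "slope")), 0.04,
               tolerance = 1e-12)
  zero <- data.frame(tau_s = tau, msd = rep(0, 7))
  expect_equal(as.numeric(diffusion_coefficient(zero)), 0)
  neg <- data.frame(tau_s = tau, msd = rev(tau))
  d <- diffusion_coefficient(neg)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "clamped"))
  expect_error(diffusion_coefficient(data.frame(tau_s = c(1, 1), msd = c(1, 2))),
               "equal")
})

test_that("ballistic MSD slope matches the closed-form OLS oracle", {
  tau <- (1:7) * 0.1
  ball <- data.frame(tau_s = tau, msd = tau^2)
  expect_equal(as.numeric(diffusion_coefficient(ball, "slope")),
               ols_slope(tau, tau^2), tolerance = 1e-12)
  expect_equal(as.numeric(diffusion_coefficient(ball)),
               ols_slope(tau, tau^2) / 4, tolerance = 1e-12)
})

test_that("max_distance and track_velocity match hand geometry", {
  tr <- data.frame(frame = 0:2, x_um = c(0, 3, 1), y_um = c(0, 4, 1))
  expect_equal(max_distance(tr), 5)
  still <- data.frame(frame = 0:5, x_um = 1, y_um = 1)
  expect_equal(max_distance(still), 0)
  expect_equal(track_velocity(still, frame_interval = 1), 0)
  # 10 um path over 5 s
  path <- data.frame(frame = 0:5, x_um = c(0, 2, 4, 6, 8, 10), y_um = 0)
  expect_equal(track_velocity(path, frame_interval = 1), 2)
  # circle traversed in T: velocity = circumference / T
  th <- seq(0, 2 * pi, length.out = 201)
  circ <- data.frame(frame = 0:200, x_um = cos(th), y_um = sin(th))
  poly_len <- sum(sqrt(diff(circ$x_um)^2 + diff(circ$y_um)^2))
  expect_equal(track_velocity(circ, frame_interval = 0.1), poly_len / 20)
})

test_that("velocity is at least the net displacement rate (path >= chord)", {
  acq <- acquisition_spec(nx = 200, ny = 200, n_frames = 50, noise = "none",
                          seed = 8)
  ts <- simulate_tracks(motion_model("brownian", D = 0.05), acq, 30)
  for (tr in split(ts$tracks, ts$tracks$track_id)) {
    elapsed <- (max(tr$frame) - min(tr$frame)) * 0.1
    expect_gte(track_velocity(tr, 0.1) + 1e-12, max_distance(tr) / elapsed)
  }
})

test_that("MSD is invariant under translation and rotation", {
  set.seed(12)
  tr <- data.frame(frame = 0:30, x_um = cumsum(rnorm(31, 0, 0.1)),
                   y_um = cumsum(rnorm(31, 0, 0.1)))
  p0 <- msd(tr, frame_interval = 0.1)
  shifted <- transform(tr, x_um = x_um + 5, y_um = y_um - 2)
  a <- 0.7
  rot <- data.frame(frame = tr$frame,
                    x_um = cos(a) * tr$x_um - sin(a) * tr$y_um,
                    y_um = sin(a) * tr$x_um + cos(a) * tr$y_um)
  expect_equal(msd(shifted, frame_interval = 0.1)$msd, p0$msd)
  expect_equal(msd(rot, frame_interval = 0.1)$msd, p0$msd)
})

test_that("median estimated D recovers the generative D within 10%", {
  acq <- acquisition_spec(nx = 600, ny = 600, n_frames = 600, noise = "none",
                          seed = 19)
  ts <- simulate_tracks(motion_model("brownian", D = 0.0067), acq, 300,
                        boundary = "none", start = "center")
  Ds <- vapply(split(ts$tracks, ts$tracks$track_id), function(tr)
    as.numeric(diffusion_coefficient(msd(tr, 7, 0.1))), numeric(1))
  expect_equal(median(Ds), 0.0067, tolerance = 0.1)
})

test_that("estimated D shrinks monotonically with tighter confinement", {
  meds <- vapply(c(2, 0.5, 0.15), function(r) {
    acq <- acquisition_spec(nx = 200, ny = 200, n_frames = 300,
                            noise = "none", seed = 101)
    ts <- simulate_tracks(motion_model("confined", D = 0.02,
                                       corral_radius = r),
                          acq, 60, start = "center")
    median(vapply(split(ts$tracks, ts$tracks$track_id), function(tr)
      as.numeric(diffusion_coefficient(msd(tr, 7, 0.1))), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("summaries aggregate per cell and flag unmapped tracks", {
  tb <- do.call(rbind, lapply(1:4, function(i)
    data.frame(track_id = i, frame = 0:25,
               x_um = cumsum(c(1, rep(0.05 * i, 25))), y_um = 1)))
  ts <- track_set(tb, 0.1)
  cm <- data.frame(track_id = 1:4, cell_id = c(1, 1, 2, 2))
  s <- summarize_dynamics(ts, cm)
  expect_equal(nrow(s$per_cell), 2)
  expect_equal(s$per_cell$n_tracks, c(2, 2))
  expect_equal(s$ensemble$velocity_um_per_s,
               median(s$per_track$velocity_um_per_s))
  expect_error(summarize_dynamics(ts, cm[-1, ]), "not mapped")
})

test_that("anchored and free populations order their summary medians correctly", {
  acq <- acquisition_spec(nx = 300, ny = 300, n_frames = 120, noise = "none",
                          seed = 55)
  free <- summarize_dynamics(simulate_tracks(
    motion_model("brownian", D = 0.02), acq, 40, start = "center"))
  anch <- summarize_dynamics(simulate_tracks(
    motion_model("confined", D = 0.02, corral_radius = 0.2), acq, 40,
    start = "center"))
  expect_gt(free$ensemble$D_um2_per_s, anch$ensemble$D_um2_per_s)
  expect_gt(free$ensemble$d_max_um, anch$ensemble$d_max_um)
})

test_that("Mann-Whitney matches brute-force enumeration on small samples", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  res <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  set.seed(42)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(0:5, na, replace = TRUE)  # ties likely
    b <- sample(0:5, nb, replace = TRUE)
    expect_equal(compare_groups(a, b)$p, mw_enum_p(a, b))
  }
})

test_that("Mann-Whitney p is symmetric and matches wilcox.test asymptotics", {
  a <- rnorm(20); b <- rnorm(15, 0.5)
  expect_equal(compare_groups(a, b)$p, compare_groups(b, a)$p)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(compare_groups(a, b)$p, ref, tolerance = 1e-12)
  expect_error(compare_groups(numeric(0), b), "non-empty")
})
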