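# Kymographs, processive-run calling, co-transport fractions.

test_that("a stationary spot gives one constant bright kymograph row", {
  acq <- acquisition_spec(nx = 80, ny = 40, n_frames = 10, noise = "none")
  ts <- track_set(data.frame(track_id = 1L, frame = 0:9, x_um = 3, y_um = 2),
                  frame_interval = 0.1)
  mv <- render_movie(ts, acq)
  ky <- make_kymograph(mv, line_roi(rbind(c(0, 2), c(7, 2))))
  rows <- apply(ky$matrix, 2, which.max)
  expect_equal(length(unique(rows)), 1)
  # the bright row sits at 3 um along the line (row index ~ 31 at 0.1 um step)
  expect_equal(ky$positions_um[rows[1]], 3, tolerance = 0.1)
})

test_that("a spot moving a pixel per frame traces a unit-slope diagonal", {
  acq <- acquisition_spec(nx = 80, ny = 40, n_frames = 25, noise = "none")
  ts <- track_set(data.frame(track_id = 1L, frame = 0:24,
                             x_um = 1 + 0.1 * (0:24), y_um = 2),
                  frame_interval = 0.1)
  mv <- render_movie(ts, acq)
  ky <- make_kymograph(mv, line_roi(rbind(c(0.5, 2), c(6.5, 2))))
  peaks <- apply(ky$matrix, 2, which.max)
  expect_equal(unname(diff(peaks)), rep(1, 24))
})

test_that("width averaging changes amplitude but not trace position", {
  acq <- acquisition_spec(nx = 80, ny = 40, n_frames = 5, noise = "none")
  ts <- track_set(data.frame(track_id = 1L, frame = 0:4,
                             x_um = 2 + 0.2 * (0:4), y_um = 2),
                  frame_interval = 0.1)
  mv <- render_movie(ts, acq)
  k1 <- make_kymograph(mv, line_roi(rbind(c(0.5, 2), c(6.5, 2)), width = 1))
  k3 <- make_kymograph(mv, line_roi(rbind(c(0.5, 2), c(6.5, 2)), width = 3))
  expect_equal(apply(k1$matrix, 2, which.max), apply(k3$matrix, 2, which.max))
  expect_true(all(k3$matrix[cbind(apply(k3$matrix, 2, which.max), 1:5)] <
                  k1$matrix[cbind(apply(k1$matrix, 2, which.max), 1:5)]))
  expect_error(make_kymograph(mv, line_roi(rbind(c(-1, 2), c(6, 2)))),
               "outside")
})

test_that("kymograph line readout converts to distance and velocity", {
  r <- run_from_kymo_line(c(1.0, 0), c(3.0, 10), frame_interval = 1)
  expect_equal(r$distance_um, 2)
  expect_equal(r$velocity_um_per_s, 0.2)
  v <- run_from_kymo_line(c(1.0, 0), c(1.0, 5), frame_interval = 0.5)
  expect_equal(v$distance_um, 0)
  expect_equal(v$velocity_um_per_s, 0)
  half <- run_from_kymo_line(c(1.0, 0), c(3.0, 10), frame_interval = 2)
  expect_equal(half$distance_um, 2)
  expect_equal(half$velocity_um_per_s, r$velocity_um_per_s / 2)
  expect_error(run_from_kymo_line(c(1, 5), c(2, 5), 1), "later frame")
})

test_that("kymograph velocity of a constant-speed spot matches the generative speed", {
  acq <- acquisition_spec(nx = 120, ny = 40, n_frames = 30, noise = "none")
  speed <- 0.7
  ts <- track_set(data.frame(track_id = 1L, frame = 0:29,
                             x_um = 1 + speed * 0.1 * (0:29), y_um = 2),
                  frame_interval = 0.1)
  mv <- render_movie(ts, acq)
  ky <- make_kymograph(mv, line_roi(rbind(c(0.5, 2), c(9.5, 2))))
  peaks <- apply(ky$matrix, 2, which.max)
  est <- run_from_kymo_line(c(ky$positions_um[peaks[1]], 0),
                            c(ky$positions_um[peaks[30]], 29),
                            ky$frame_interval)
  expect_equal(est$velocity_um_per_s, speed,
               tolerance = ky$position_step / (speed * 0.1) / 29)
})

test_that("processive-run calling finds monotone excursions above threshold", {
  run3 <- data.frame(frame = 0:30, x_um = seq(0, 3, length.out = 31), y_um = 0)
  r <- call_processive_runs(run3)
  expect_equal(nrow(r), 1)
  expect_equal(r$displacement_um, 3)
  short <- data.frame(frame = 0:30, x_um = seq(0, 1.5, length.out = 31),
                      y_um = 0)
  expect_equal(nrow(call_processive_runs(short)), 0)
  osc <- data.frame(frame = 0:40, x_um = rep(c(0, 1), length.out = 41),
                    y_um = 0)
  expect_equal(nrow(call_processive_runs(osc)), 0)
})

test_that("run calling matches a brute-force scan over monotone segments", {
  set.seed(9)
  for (rep in 1:10) {
    x <- cumsum(rnorm(60, 0, 0.6))
    tr <- data.frame(frame = 0:59, x_um = x, y_um = 0)
    runs <- call_processive_runs(tr, min_run = 2)
    # oracle: enumerate all maximal monotone segments of x directly
    s <- sign(diff(x))
    brk <- c(0, which(diff(s) != 0 & s[-1] != 0 & s[-length(s)] != 0), length(s))
    # simpler oracle: walk and split at strict direction reversals
    segs <- list(); start <- 1; dir <- sign(x[2] - x[1])
    for (i in 2:(length(x) - 1)) {
      d <- sign(x[i + 1] - x[i])
      if (d != 0 && dir != 0 && d != dir) {
        segs[[length(segs) + 1]] <- c(start, i)
        start <- i
      }
      if (d != 0) dir <- d
    }
    segs[[length(segs) + 1]] <- c(start, length(x))
    disp <- vapply(segs, function(se) abs(x[se[2]] - x[se[1]]), numeric(1))
    expect_equal(nrow(runs), sum(disp >= 2))
    expect_equal(sort(runs$displacement_um), sort(disp[disp >= 2]))
  }
})

test_that("run direction reverses with the excursion and respects bidirectional tracks", {
  x <- c(seq(0, 3, length.out = 16), seq(3, -1, length.out = 21)[-1])
  tr <- data.frame(frame = seq_along(x) - 1, x_um = x, y_um = 0)
  runs <- call_processive_runs(tr)
  expect_equal(nrow(runs), 2)
  expect_equal(sort(runs$displacement_um), c(3, 4))
  expect_setequal(runs$direction, c(-1, 1))
})

test_that("co-transport fraction handles identical, empty, and half-matched channels", {
  mk <- function(ids, offset = 0) {
    tb <- do.call(rbind, lapply(ids, function(i)
      data.frame(track_id = i, frame = 0:29,
                 x_um = i * 10 + seq(0, 3, length.out = 30) + offset,
                 y_um = 1)))
    track_set(tb, 0.1)
  }
  ref <- mk(1:6)
  expect_equal(cotransport_fraction(ref, ref)$fraction, 1)
  far <- mk(1:6, offset = 100)
  expect_equal(cotransport_fraction(ref, far)$fraction, 0)
  half <- mk(1:3)
  expect_equal(cotransport_fraction(ref, half)$fraction, 0.5)
  none <- track_set(data.frame(track_id = integer(0), frame = integer(0),
                               x_um = numeric(0), y_um = numeric(0)), 0.1)
  expect_equal(cotransport_fraction(ref, none)$fraction, 0)
  expect_error(cotransport_fraction(none, ref), "empty")
})

test_that("co-transport fraction is invariant to partner relabeling", {
  mk <- function(perm) {
    tb <- do.call(rbind, lapply(1:4, function(i)
      data.frame(track_id = perm[i], frame = 0:29,
                 x_um = i * 8 + seq(0, 2.5, length.out = 30), y_um = 1)))
    track_set(tb, 0.1)
  }
  ref <- mk(1:4)
  expect_equal(cotransport_fraction(ref, mk(c(3, 1, 4, 2)))$fraction,
               cotransport_fraction(ref, mk(1:4))$fraction)
})
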