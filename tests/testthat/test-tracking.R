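# Background correction, spot detection, linking, track filtering.

test_that("rolling-ball subtraction removes flat background exactly", {
  img <- matrix(10, 20, 20)
  expect_true(all(rolling_ball_subtract(img, 3) == 0))
})

test_that("rolling-ball retains an isolated spike and matches an opening oracle", {
  img <- matrix(10, 21, 21)
  img[11, 11] <- 50
  out <- rolling_ball_subtract(img, 3)
  expect_equal(out[11, 11], 40)
  expect_true(all(out[-11, ] == 0) && all(out[11, -11] == 0))
  # oracle: opening = dilate(erode); erosion kills the spike, so the
  # background estimate is the flat 10 and the residual is img - 10
  expect_equal(out, pmax(img - 10, 0))
})

test_that("rolling-ball validates its radius", {
  expect_error(rolling_ball_subtract(matrix(1, 5, 5), 0.5), "radius")
  expect_error(rolling_ball_subtract(matrix(1, 5, 5), 6), "smaller")
})

test_that("blank frames yield zero spots and tiny diameters are rejected", {
  acq <- acquisition_spec(nx = 40, ny = 40, n_frames = 2, noise = "none")
  mv <- movie_stack(array(3, dim = c(40, 40, 2)), 0.1, 0.1)
  expect_equal(nrow(detect_spots(mv)), 0)
  expect_error(detect_spots(mv, diameter = 0.01), "at least one pixel")
})

test_that("a single rendered spot is found within 0.5 px of the truth", {
  acq <- acquisition_spec(nx = 64, ny = 64, n_frames = 1, noise = "none")
  truth <- c(x = 3.27, y = 2.84)
  ts <- track_set(data.frame(track_id = 1L, frame = 0L, x_um = truth["x"],
                             y_um = truth["y"]), frame_interval = 0.1)
  mv <- render_movie(ts, acq)
  sp <- detect_spots(mv)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um - truth["x"]) / 0.1, 0.5)
  expect_lt(abs(sp$y_um - truth["y"]) / 0.1, 0.5)
})

test_that("two spots 3 um apart are resolved as two detections", {
  acq <- acquisition_spec(nx = 80, ny = 80, n_frames = 1, noise = "none")
  ts <- track_set(data.frame(track_id = 1:2, frame = 0L,
                             x_um = c(2, 5), y_um = c(4, 4)),
                  frame_interval = 0.1)
  sp <- detect_spots(render_movie(ts, acq))
  expect_equal(nrow(sp), 2)
})

test_that("linking follows a moving spot and never merges distant ones", {
  sp <- data.frame(frame = rep(0:9, 2),
                   x_um = c(1 + 0.1 * (0:9), rep(6, 10)),
                   y_um = c(rep(2, 10), rep(2, 10)))
  ts <- link_spots(sp, max_displacement = 0.3)
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  lens <- table(ts$tracks$track_id)
  expect_true(all(lens == 10))
})

test_that("a missing middle frame splits a track (no gap closing)", {
  sp <- data.frame(frame = c(0:4, 6:9), x_um = 1, y_um = 1)
  ts <- link_spots(sp, max_displacement = 0.3)
  expect_equal(length(unique(ts$tracks$track_id)), 2)
})

test_that("linking is invariant to the input row order", {
  set.seed(3)
  sp <- data.frame(frame = rep(0:5, each = 3),
                   x_um = rep(c(1, 3, 5), 6) + rnorm(18, 0, 0.02),
                   y_um = rep(c(1, 2, 3), 6) + rnorm(18, 0, 0.02))
  t1 <- link_spots(sp, 0.5)
  t2 <- link_spots(sp[sample(nrow(sp)), ], 0.5)
  expect_identical(t1$tracks, t2$tracks)
})

test_that("track-length filter keeps >20-frame tracks only and is idempotent", {
  tb <- rbind(data.frame(track_id = 1L, frame = 0:19, x_um = 0, y_um = 0),
              data.frame(track_id = 2L, frame = 0:20, x_um = 1, y_um = 1))
  ts <- track_set(tb, 0.1)
  f1 <- filter_tracks(ts)  # default min_frames = 21
  expect_equal(unique(f1$tracks$track_id), 2L)
  f2 <- filter_tracks(f1)
  expect_identical(f1$tracks, f2$tracks)
  empty <- filter_tracks(track_set(tb[0, ], 0.1))
  expect_equal(nrow(empty$tracks), 0)
})

test_that("noise-free pipeline reproduces ground-truth tracks to sub-pixel accuracy", {
  fx <- grid_movie(n_tracks = 6, n_frames = 40, seed = 7)
  sp <- detect_spots(fx$movie)
  lk <- filter_tracks(link_spots(sp, 0.5, 0.1), 21)
  expect_equal(length(unique(lk$tracks$track_id)), 6)
  err <- vapply(split(lk$tracks, lk$tracks$track_id), function(tr) {
    e <- vapply(seq_len(nrow(tr)), function(i) {
      g <- fx$tracks$tracks[fx$tracks$tracks$frame == tr$frame[i], ]
      min(sqrt((g$x_um - tr$x_um[i])^2 + (g$y_um - tr$y_um[i])^2))
    }, numeric(1))
    sqrt(mean(e^2))
  }, numeric(1))
  expect_lt(max(err) / 0.1, 0.5)  # RMS error under half a pixel
})
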