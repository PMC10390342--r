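make_track <- function(id, n, x0 = 0, y0 = 0, dx = 1, dy = 0, frame0 = 1) {
  data.frame(track_id = id, frame = frame0 + seq_len(n) - 1,
             x_um = x0 + (seq_len(n) - 1) * dx,
             y_um = y0 + (seq_len(n) - 1) * dy)
}

test_that("track filtering is strict in min_frames and windows correctly", {
  short <- make_track(1, 9)
  long <- make_track(2, 12)
  exactly10 <- make_track(3, 10)
  sets <- filter_and_window_tracks(rbind(short, long, exactly10),
                                   min_frames = 10,
                                   windows = list(c(0, 200)),
                                   region_boundary_um = 1e6)
  kept <- unique(sets$window1_head$track_id)
  expect_identical(kept, 2)             # "longer than 10 frames" is strict

  # 50 long + 50 short synthetic cohort
  cohort <- do.call(rbind, c(
    lapply(1:50, function(i) make_track(i, 15, y0 = i)),
    lapply(51:100, function(i) make_track(i, 5, y0 = i))))
  sets <- filter_and_window_tracks(cohort, windows = list(c(0, 200)),
                                   region_boundary_um = 1e6)
  expect_equal(length(unique(sets$window1_head$track_id)), 50)
})

test_that("windowing restricts samples and assigns regions by mean position", {
  tr <- rbind(make_track(1, 30, x0 = 10),    # head side (x < 100 on average)
              make_track(2, 30, x0 = 200))   # tail side
  sets <- filter_and_window_tracks(tr, windows = list(c(0, 150), c(160, 290)),
                                   region_boundary_um = 100,
                                   frame_interval_min = 10)
  expect_setequal(names(sets), c("window1_head", "window1_tail",
                                 "window2_head", "window2_tail"))
  expect_true(all(sets$window1_head$track_id == 1))
  expect_true(all(sets$window1_tail$track_id == 2))
  # within-window portions only
  expect_lte(max(sets$window1_head$frame), 16)
  expect_warning(
    filter_and_window_tracks(tr, windows = list(c(5000, 6000))),
    "outside the recording")
})

test_that("directionality angles follow the head-to-tail zero convention", {
  # head->tail drift (+x) -> angle 0
  ht <- do.call(rbind, lapply(1:5, function(i) make_track(i, 12, y0 = i)))
  s <- track_directionality(ht)
  expect_equal(unname(s$angles_rad), rep(0, 5))
  expect_equal(sum(s$histogram), s$n_tracks)
  # tail->head drift (-x) -> angle pi
  th <- do.call(rbind, lapply(1:5, function(i)
    make_track(i, 12, y0 = i, dx = -1)))
  expect_equal(unname(track_directionality(th)$angles_rad), rep(pi, 5))
})

test_that("mean average velocity uses path length over duration", {
  # zig-zag track: path 10 um over 5 frames (40 min), net displacement ~0
  zz <- data.frame(track_id = 1, frame = 1:5,
                   x_um = c(0, 2.5, 0, 2.5, 0), y_um = 0)
  s <- track_directionality(zz, frame_interval_min = 10)
  expect_equal(s$mean_velocity_um_min, 10 / 40)
  # time reversal leaves velocity unchanged, flips the angle by pi
  fwd <- make_track(1, 6, dx = 2, dy = 1)
  rev <- fwd; rev$frame <- rev(fwd$frame)
  sf <- track_directionality(fwd); sr <- track_directionality(rev)
  expect_equal(sf$mean_velocity_um_min, sr$mean_velocity_um_min)
  expect_equal((sf$angles_rad - sr$angles_rad) %% (2 * pi), pi,
               ignore_attr = TRUE)
})

test_that("zero net displacement is excluded and counted separately", {
  loop <- data.frame(track_id = 1, frame = 1:5,
                     x_um = c(0, 1, 1, 0, 0), y_um = c(0, 0, 1, 1, 0))
  s <- track_directionality(loop)
  expect_equal(s$n_zero, 1L)
  expect_equal(s$n_tracks, 0L)
  expect_equal(sum(s$histogram), 0L)
})

test_that("isotropic random walks have a small mean resultant length", {
  tr <- generate_tracks(flow_spec("zero"), n_tracks = 300, n_frames = 15,
                        jitter_sd = 1, seed = 17)
  s <- track_directionality(tr)
  expect_lt(s$resultant_length, 0.2)
})

test_that("the polar histogram is equivariant under rotation of all tracks", {
  tr <- generate_tracks(flow_spec("zero"), n_tracks = 100, n_frames = 10,
                        jitter_sd = 1, seed = 23)
  s0 <- track_directionality(tr, bin_width_deg = 45)
  a <- pi / 2   # rotate by exactly two 45-degree bins
  rot <- tr
  rot$x_um <- cos(a) * tr$x_um - sin(a) * tr$y_um
  rot$y_um <- sin(a) * tr$x_um + cos(a) * tr$y_um
  s1 <- track_directionality(rot, bin_width_deg = 45)
  expect_equal(s1$histogram, s0$histogram[c(7:8, 1:6)])
})
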