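test_that("intensity time course averages frames and smooths as configured", {
  arr <- array(3, c(8, 8, 12))
  tr <- intensity_timecourse(image_stack(arr, 1, 2))
  expect_equal(tr$intensity, rep(3, 12))
  expect_equal(tr$window, 10)

  # exponential course: smoothed trace within 1% of analytic away from edges
  k <- 0.005
  times <- seq(0, 178, by = 2)
  vals <- exp(k * times)
  arr2 <- array(rep(vals, each = 16), c(4, 4, length(times)))
  tr2 <- intensity_timecourse(image_stack(arr2, 1, 2))
  core <- 10:80
  expect_equal(tr2$intensity[core] / vals[core], rep(1, length(core)),
               tolerance = 0.01)
})

test_that("AP profile discards bright puncta and recovers gradients", {
  flat <- matrix(1, 40, 100)
  pf <- ap_profile(flat, pixel_size_um = 1, window_um = 10)
  expect_equal(pf$intensity, rep(1, 100))

  # head-to-tail linear gradient plus 10x puncta
  grad <- matrix(rep(seq(2, 1, length.out = 300), each = 60), 60, 300)
  set.seed(51)
  puncta <- cbind(sample(60, 40, TRUE), sample(300, 40, TRUE))
  img <- grad
  img[puncta] <- 20
  pf <- ap_profile(img, pixel_size_um = 1, window_um = 20)
  core <- 30:270
  fit <- stats::coef(stats::lm(pf$intensity[core] ~ pf$position_um[core]))
  true_slope <- (1 - 2) / 299
  expect_equal(unname(fit[2]), true_slope, tolerance = abs(true_slope) * 0.05)

  # scale invariance of the relative discard rule
  pf2 <- ap_profile(img * 37, pixel_size_um = 1, window_um = 20)
  expect_equal(pf2$intensity, 37 * pf$intensity, tolerance = 1e-12)

  # quantile reading of the threshold is available behind the switch
  pq <- ap_profile(img, pixel_size_um = 1, window_um = 20,
                   discard_mode = "quantile", discard_fraction = 0.85)
  expect_lt(max(pq$intensity, na.rm = TRUE), 3)
})

test_that("tail displacement traces are translation-invariant with zero start", {
  static <- data.frame(frame = 1:20, x_um = 5, y_um = 7)
  tr <- tail_displacement(static)
  expect_equal(tr$displacement_um, rep(0, 20))

  moving <- data.frame(frame = 1:60, x_um = 100 - (0:59) * 1, y_um = 3)
  tr2 <- tail_displacement(moving, frame_interval_min = 2)
  expect_equal(tr2$displacement_um[1], 0)
  expect_equal(diff(tr2$displacement_um), rep(1, 59))   # 0.5 um/min * 2 min
  expect_equal(tr2$rate_um_min[10:50], rep(0.5, 41))

  shifted <- moving
  shifted$x_um <- shifted$x_um + 55; shifted$y_um <- shifted$y_um - 12
  expect_equal(tail_displacement(shifted)$displacement_um,
               tr2$displacement_um)
})

test_that("rate exactly proportional to intensity gives r = 1", {
  k <- 0.01
  t <- seq(0, 200, by = 2)
  inten <- intensity_trace(t, exp(k * t), window = 1)
  disp <- (exp(k * t) - 1) / k   # derivative proportional to intensity
  cond <- condensation_trace(t, disp, rate_window = 1)
  # interior samples: central differences of an exponential are exactly
  # proportional to it (sinh factor); the one-sided edges are excluded
  r <- intensity_rate_correlation(inten, cond, t_range = c(2, 198))$pearson_r
  expect_equal(r, 1, tolerance = 1e-10)
})

test_that("the default noisy scene correlates above 0.9 over phase 1", {
  sc <- generate_condensation_scene(noise_sd = 0.05, seed = 12)
  tr <- intensity_trace(sc$times_min, sc$col4_intensity)
  cd <- condensation_trace(sc$times_min, sc$tail_displacement_um)
  r <- intensity_rate_correlation(tr, cd,
                                  t_range = c(0, sc$phase_boundaries_min[1]))
  expect_gt(r$pearson_r, 0.9)
})

test_that("independent white-noise traces stay decorrelated", {
  rs <- vapply(1:20, function(s) {
    x <- vncmorph:::with_seed(s, stats::rnorm(90))
    y <- vncmorph:::with_seed(s + 1000, stats::rnorm(90))
    t <- seq(0, by = 2, length.out = 90)
    intensity_rate_correlation(
      intensity_trace(t, 10 + x, window = 1),
      condensation_trace(t, cumsum(abs(y)), rate_window = 1))$pearson_r
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.3), 0.95 - 1e-9)
})

test_that("zero-variance input flags the correlation undefined", {
  t <- seq(0, 60, by = 2)
  inten <- intensity_trace(t, rep(5, length(t)), window = 1)
  cond <- condensation_trace(t, seq(0, 30, length.out = length(t)),
                             rate_window = 1)
  expect_warning(out <- intensity_rate_correlation(inten, cond),
                 "zero-variance")
  expect_true(is.na(out$pearson_r))
})
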