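test_that("parameter presets match the optimised acquisition settings", {
  pw <- piv_preset("confocal_whole")
  expect_equal(c(pw$source_size, pw$search_size, pw$grid_size,
                 pw$corr_threshold), c(9, 16, 5, 0.5))
  ph <- piv_preset("confocal_hires")
  expect_equal(c(ph$source_size, ph$search_size, ph$grid_size,
                 ph$corr_threshold), c(2, 4, 1, 0.3))
  pm <- piv_preset("mosaic")
  expect_equal(c(pm$source_size, pm$search_size, pm$grid_size,
                 pm$corr_threshold), c(5, 10, 3, 0.5))
  kw <- kernel_preset("whole_tissue")
  expect_equal(c(kw$spatial_size, kw$spatial_sigma, kw$temporal_size,
                 kw$temporal_sigma), c(50, 10, 90, 40))
  expect_equal(kw$temporal_unit, "min")
  kh <- kernel_preset("hires")
  expect_equal(c(kh$spatial_size, kh$spatial_sigma, kh$temporal_size,
                 kh$temporal_sigma), c(10, 2, 5, 2))
  expect_equal(kh$temporal_unit, "frames")
})

test_that("identical frames give zero displacement everywhere", {
  s <- shifted_speckle_stack(shift_px = 0, seed = 4)
  pv <- compute_piv(s, piv_preset("confocal_whole"))
  expect_true(all(pv$valid))
  expect_lt(max(abs(pv$u)), 0.05 * s$pixel_size_um)
  expect_lt(max(abs(pv$v)), 0.05 * s$pixel_size_um)
})

test_that("all presets recover a uniform integer shift to <= 0.2 px RMS", {
  cases <- list(
    list(preset = "confocal_whole", px = 0.5, shape = c(160, 160), shift = 3),
    list(preset = "confocal_hires", px = 0.2, shape = c(128, 128), shift = 2),
    list(preset = "mosaic",         px = 0.25, shape = c(160, 160), shift = 3))
  for (cs in cases) {
    s <- shifted_speckle_stack(shift_px = cs$shift, pixel_size_um = cs$px,
                               shape = cs$shape, seed = 21)
    pv <- compute_piv(s, piv_preset(cs$preset))
    expect_gt(mean(pv$valid), 0.9)
    err_u <- (pv$u[pv$valid] - cs$shift * cs$px) / cs$px
    err_v <- pv$v[pv$valid] / cs$px
    expect_lt(sqrt(mean(err_u^2)), 0.2)
    expect_lt(sqrt(mean(err_v^2)), 0.2)
  }
})

test_that("vector validity fraction is non-increasing in corr_threshold", {
  s <- shifted_speckle_stack(shift_px = 2, seed = 8, noise_sd = 0.3)
  fracs <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th) {
    p <- piv_params(9, 16, 5, corr_threshold = th)
    mean(compute_piv(s, p)$valid)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("rotating the stack by 90 degrees rotates the recovered field", {
  s <- shifted_speckle_stack(shift_px = 3, shape = c(128, 128), seed = 13)
  rot <- s
  # 90 deg counter-clockwise: new[r, c] = old[c, H + 1 - r]
  rot$data <- aperm(s$data, c(2, 1, 3))[, dim(s$data)[1]:1, , drop = FALSE]
  p0 <- compute_piv(s, piv_preset("confocal_whole"))
  p90 <- compute_piv(rot, piv_preset("confocal_whole"))
  # old (row j, col i) maps to new (row i, col H+1-j): a +x displacement
  # becomes a +y displacement
  expect_equal(mean(p90$v[p90$valid]), mean(p0$u[p0$valid]), tolerance = 0.05)
  expect_lt(abs(mean(p90$u[p90$valid])), 0.05)
})

test_that("degenerate windows are flagged invalid, never NaN-poisoned", {
  arr <- array(0, c(64, 64, 2))
  arr[20:30, 20:30, ] <- 1   # texture only in one corner
  s <- image_stack(arr, 0.5, 1)
  pv <- compute_piv(s, piv_params(4, 8, 4, corr_threshold = 0.5))
  expect_true(any(!pv$valid))            # constant windows exist
  expect_false(any(is.nan(pv$u)))
  expect_true(all(is.na(pv$u[!pv$valid])))
})

test_that("oversized windows and short stacks are configuration errors", {
  s <- shifted_speckle_stack(shape = c(32, 32))
  expect_error(compute_piv(s, piv_params(9, 40, 5)), "larger than image")
  one <- image_stack(array(1, c(32, 32, 1)), 0.5, 1)
  expect_error(compute_piv(one, piv_preset("confocal_whole")), "2 frames")
})

test_that("ROI masking invalidates vectors whose source leaves the ROI", {
  s <- shifted_speckle_stack(shift_px = 2, seed = 5)
  roi <- matrix(TRUE, 128, 128)
  roi[, 1:64] <- FALSE
  pv <- compute_piv(s, piv_preset("confocal_whole"), roi_mask = roi)
  in_left <- pv$x_um < 64 * 0.5 - 9 / 2
  expect_true(all(!pv$valid[, in_left, ]))
  expect_true(any(pv$valid[, !in_left, ]))
})

test_that("interpolation leaves a uniform field unchanged", {
  f <- uniform_field(1.2, -0.4, nt = 5)
  out <- interpolate_field_series(f, interpolation_kernel(10, 3, 4, 2, "frames"))
  expect_true(all(out$valid))
  expect_equal(out$u, f$u, tolerance = 1e-12)
  expect_equal(out$v, f$v, tolerance = 1e-12)
})

test_that("a single valid vector fills its truncation window as sole contributor", {
  f <- uniform_field(0, 0, nx = 9, ny = 9, nt = 1, spacing = 2)
  f$valid[] <- FALSE
  f$u[] <- NA; f$v[] <- NA
  f$u[5, 5, 1] <- 0.7; f$v[5, 5, 1] <- -0.2; f$valid[5, 5, 1] <- TRUE
  out <- interpolate_field_series(f, interpolation_kernel(8, 2, 2, 1, "frames"))
  # within 4 um of the centre node: the sole contributor's value
  d <- sqrt(outer((f$y_um - f$y_um[5])^2, (f$x_um - f$x_um[5])^2, "+"))
  inside <- d <= 4
  expect_true(all(out$u[, , 1][inside] == 0.7))
  expect_true(all(is.na(out$u[, , 1][!inside])))
  expect_true(all(out$valid[, , 1] == inside))
})

test_that("interpolated components stay within the convex hull of inputs", {
  set.seed(31)
  u <- array(stats::rnorm(9 * 9 * 4), c(9, 9, 4))
  v <- array(stats::rnorm(9 * 9 * 4), c(9, 9, 4))
  valid <- array(stats::runif(9 * 9 * 4) > 0.3, c(9, 9, 4))
  u[!valid] <- NA; v[!valid] <- NA
  f <- field_series((0:8) * 3, (0:8) * 3, u, v, valid)
  out <- interpolate_field_series(f, interpolation_kernel(20, 6, 6, 3, "frames"))
  expect_true(all(out$u[out$valid] <= max(u, na.rm = TRUE) + 1e-12))
  expect_true(all(out$u[out$valid] >= min(u, na.rm = TRUE) - 1e-12))
  expect_true(all(out$v[out$valid] <= max(v, na.rm = TRUE) + 1e-12))
  expect_true(all(out$v[out$valid] >= min(v, na.rm = TRUE) - 1e-12))
})

test_that("a kernel smaller than the grid spacing warns", {
  f <- uniform_field(1, 0, spacing = 10)
  expect_warning(
    interpolate_field_series(f, interpolation_kernel(5, 2, 4, 2, "frames")),
    "nearest-neighbour")
})
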