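#' Whole-frame intensity time course
#'
#' Per-frame spatial mean intensity of a stack, smoothed with a centred
#' moving average (default 10 frames, matching the 2-min-resolution
#' collagen-IV induction traces).
#'
#' @param stack an [image_stack].
#' @param window smoothing window in frames.
#' @return object of class `intensity_trace`: list with `times_min`,
#'   `intensity` (smoothed), `raw`, `window`.
#' @export
intensity_timecourse <- function(stack, window = 10) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- dim(stack$data)[3]
  raw <- vapply(seq_len(nt), function(t) mean(stack$data[, , t]), numeric(1))
  times <- (seq_len(nt) - 1) * stack$frame_interval_min
  structure(list(times_min = times, intensity = moving_average(raw, window),
                 raw = raw, window = window),
            class = "intensity_trace")
}

#' Intensity trace from a precomputed per-frame series
#'
#' @param times_min strictly increasing times (min).
#' @param values per-frame mean intensities.
#' @param window smoothing window in frames (default 10).
#' @return an `intensity_trace`.
#' @export
intensity_trace <- function(times_min, values, window = 10) {
  stopifnot(length(times_min) == length(values), all(diff(times_min) > 0))
  structure(list(times_min = times_min,
                 intensity = moving_average(values, window),
                 raw = values, window = window),
            class = "intensity_trace")
}

#' Anteroposterior intensity profile with bright-object rejection
#'
#' Removes intracellular collagen puncta (hemocytes) by discarding pixels
#' brighter than `discard_fraction` of the image's intensity range (i.e.
#' above `min + discard_fraction * (max - min)`; hemocyte puncta are the
#' brightest objects), averages the remaining pixels per AP-axis column,
#' and smooths with a walking average over `window_um`. The discard rule
#' is relative, so the profile is invariant to positive rescaling of the
#' image, and a uniform image keeps all pixels.
#'
#' `discard_mode = "quantile"` offers an alternative reading in which the
#' threshold is the `discard_fraction` quantile of the cumulative
#' intensity histogram.
#'
#' @param image matrix `[H, W]` (or one frame of a stack).
#' @param pixel_size_um um per pixel.
#' @param discard_fraction threshold fraction (default 0.7).
#' @param window_um walking-average window (default 200 um).
#' @param discard_mode `"max"` (default) or `"quantile"`.
#' @return data.frame `position_um, intensity`.
#' @export
ap_profile <- function(image, pixel_size_um = 1, discard_fraction = 0.7,
                       window_um = 200, discard_mode = c("max", "quantile")) {
  discard_mode <- match.arg(discard_mode)
  if (inherits(image, "image_stack")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$data[, , 1]
  }
  thr <- switch(discard_mode,
    max = min(image) + discard_fraction * (max(image) - min(image)),
    quantile = stats::quantile(image, discard_fraction, names = FALSE))
  keep <- image <= thr
  if (!any(keep)) stop_config("all pixels discarded by the intensity threshold")
  masked <- image
  masked[!keep] <- NA
  prof <- colMeans(masked, na.rm = TRUE)
  prof[is.nan(prof)] <- NA
  win_px <- max(1L, round(window_um / pixel_size_um))
  data.frame(position_um = (seq_along(prof) - 1) * pixel_size_um,
             intensity = moving_average(prof, win_px))
}

#' Tail-displacement condensation trace from clicked positions
#'
#' Converts a manually tracked tail-position table (`frame, x, y` at the
#' native 2-min resolution) into a displacement trace relative to the
#' first frame, either as the Euclidean distance or as the projection on
#' the AP axis, and a condensation rate by central differences.
#'
#' @param points data.frame `frame, x_um, y_um` (or `x, y`).
#' @param frame_interval_min minutes per frame (default 2).
#' @param projection `"euclidean"` or `"ap_axis"` (displacement along -x,
#'   i.e. positive when the tail moves head-ward).
#' @param rate_window smoothing window (frames) applied to the rate
#'   (default 10, matching the intensity smoothing).
#' @return object of class `condensation_trace`: list with `times_min`,
#'   `displacement_um` (first entry 0), `rate_um_min`.
#' @export
tail_displacement <- function(points, frame_interval_min = 2,
                              projection = c("euclidean", "ap_axis"),
                              rate_window = 10) {
  projection <- match.arg(projection)
  nm <- names(points)
  xc <- if ("x_um" %in% nm) "x_um" else "x"
  yc <- if ("y_um" %in% nm) "y_um" else "y"
  pts <- points[order(points$frame), , drop = FALSE]
  x <- pts[[xc]]; y <- pts[[yc]]
  disp <- switch(projection,
    euclidean = sqrt((x - x[1])^2 + (y - y[1])^2),
    ap_axis = -(x - x[1]))
  times <- (pts$frame - pts$frame[1]) * frame_interval_min
  n <- length(disp)
  rate <- numeric(n)
  if (n >= 3) {
    rate[2:(n - 1)] <- (disp[3:n] - disp[1:(n - 2)]) /
      (times[3:n] - times[1:(n - 2)])
    rate[1] <- (disp[2] - disp[1]) / (times[2] - times[1])
    rate[n] <- (disp[n] - disp[n - 1]) / (times[n] - times[n - 1])
  }
  structure(list(times_min = times, displacement_um = disp,
                 rate_um_min = moving_average(rate, rate_window)),
            class = "condensation_trace")
}

#' Build a condensation trace from a displacement series
#'
#' @param times_min times (min).
#' @param displacement_um displacement relative to the first sample.
#' @param rate_window rate smoothing window (frames).
#' @return a `condensation_trace`.
#' @export
condensation_trace <- function(times_min, displacement_um, rate_window = 10) {
  stopifnot(length(times_min) == length(displacement_um))
  disp <- displacement_um - displacement_um[1]
  n <- length(disp)
  rate <- numeric(n)
  if (n >= 3) {
    rate[2:(n - 1)] <- (disp[3:n] - disp[1:(n - 2)]) /
      (times_min[3:n] - times_min[1:(n - 2)])
    rate[1] <- (disp[2] - disp[1]) / (times_min[2] - times_min[1])
    rate[n] <- (disp[n] - disp[n - 1]) / (times_min[n] - times_min[n - 1])
  }
  structure(list(times_min = times_min, displacement_um = disp,
                 rate_um_min = moving_average(rate, rate_window)),
            class = "condensation_trace")
}

#' Correlate intensity with condensation rate
#'
#' Resamples an intensity trace and a condensation trace to their common
#' time range (linear interpolation onto the rate trace's time base) and
#' reports the paired series plus the Pearson correlation coefficient.
#' Purely descriptive: no causal claim is made.
#'
#' @param trace an `intensity_trace`.
#' @param cond a `condensation_trace`.
#' @param t_range optional `(t0, t1)` window (min) over which to correlate.
#' @return list with `pairs` (data.frame `time_min, intensity,
#'   rate_um_min`) and `pearson_r` (`NA` with a warning for zero-variance
#'   input).
#' @export
intensity_rate_correlation <- function(trace, cond, t_range = NULL) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(cond, "condensation_trace"))
  t0 <- max(min(trace$times_min), min(cond$times_min))
  t1 <- min(max(trace$times_min), max(cond$times_min))
  if (!is.null(t_range)) { t0 <- max(t0, t_range[1]); t1 <- min(t1, t_range[2]) }
  tt <- cond$times_min[cond$times_min >= t0 & cond$times_min <= t1]
  if (length(tt) < 3) stop_config("traces share fewer than 3 time points")
  ii <- stats::approx(trace$times_min, trace$intensity, xout = tt)$y
  rr <- stats::approx(cond$times_min, cond$rate_um_min, xout = tt)$y
  ok <- is.finite(ii) & is.finite(rr)
  pairs <- data.frame(time_min = tt[ok], intensity = ii[ok],
                      rate_um_min = rr[ok])
  r <- if (stats::sd(pairs$intensity) == 0 || stats::sd(pairs$rate_um_min) == 0) {
    warning("zero-variance input: correlation undefined")
    NA_real_
  } else stats::cor(pairs$intensity, pairs$rate_um_min)
  list(pairs = pairs, pearson_r = r)
}
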