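#' Photobleached-stripe displacement analysis
#'
#' Quantifies anisotropic tissue-surface motion from a patterned
#' photobleach: two midline intensity profiles (immediately after
#' bleaching and a later timepoint) are each normalised to their own mean,
#' smoothed with a walking average (default 150 data points), and their
#' local minima — the stripe centres — detected with a prominence floor
#' and refined to sub-sample precision by a parabolic fit. Minima are
#' paired by rank order between timepoints and the per-stripe displacement
#' is `position_t1 - position_t0`; with the head at the coordinate origin,
#' negative displacements are head-ward motion.
#'
#' @param profile_t0,profile_t1 numeric intensity profiles on a common
#'   spatial axis (linescan means, extracted upstream when starting from
#'   images).
#' @param position_um sample positions (um); defaults to 0.108-um spacing.
#' @param smooth_points walking-average window in samples (default 150).
#' @param min_prominence minimum dip prominence as a fraction of the
#'   smoothed profile range (default 0.05).
#' @param expected_stripes optional expected stripe count; mismatch warns.
#' @return object of class `stripe_analysis`: list with `minima_t0_um`,
#'   `minima_t1_um`, `displacement_um`, and a `stripes` data.frame
#'   (`stripe_index, pos_t0_um, pos_t1_um, displacement_um`).
#' @export
stripe_analysis <- function(profile_t0, profile_t1,
                            position_um = (seq_along(profile_t0) - 1) * 0.108,
                            smooth_points = 150, min_prominence = 0.05,
                            expected_stripes = NULL) {
  stopifnot(length(profile_t0) == length(profile_t1),
            length(position_um) == length(profile_t0))
  prep <- function(p) moving_average(p / mean(p), smooth_points)
  s0 <- prep(profile_t0); s1 <- prep(profile_t1)
  m0 <- find_profile_minima(s0, position_um, min_prominence)
  m1 <- find_profile_minima(s1, position_um, min_prominence)
  if (length(m0) != length(m1))
    stop_config("unequal stripe counts between timepoints: %d vs %d",
                length(m0), length(m1))
  if (!is.null(expected_stripes) && length(m0) != expected_stripes)
    warning(sprintf("detected %d stripes, expected %d",
                    length(m0), expected_stripes))
  disp <- m1 - m0
  structure(list(minima_t0_um = m0, minima_t1_um = m1,
                 displacement_um = disp,
                 stripes = data.frame(stripe_index = seq_along(m0),
                                      pos_t0_um = m0, pos_t1_um = m1,
                                      displacement_um = disp),
                 smooth_points = smooth_points,
                 profiles = list(t0 = s0, t1 = s1, position_um = position_um)),
            class = "stripe_analysis")
}

# Local minima of a smoothed profile with a prominence floor (fraction of
# profile range); positions refined by a 3-point parabolic fit.
find_profile_minima <- function(p, pos, min_prominence) {
  n <- length(p)
  if (n < 3) return(numeric(0))
  rng <- diff(range(p, na.rm = TRUE))
  if (rng == 0) return(numeric(0))
  is_min <- which(p[2:(n - 1)] < p[1:(n - 2)] & p[2:(n - 1)] <= p[3:n]) + 1L
  out <- numeric(0)
  for (i in is_min) {
    # topographic prominence (for minima): on each side, the wall is the
    # highest point between the minimum and the nearest strictly lower
    # sample (or the end of the profile)
    lower_l <- which(p[seq_len(i - 1)] < p[i])
    wall_l <- max(p[(if (length(lower_l)) max(lower_l) + 1L else 1L):(i - 1)],
                  na.rm = TRUE)
    lower_r <- which(p[(i + 1):n] < p[i])
    r_end <- if (length(lower_r)) i + min(lower_r) - 1L else n
    wall_r <- max(p[(i + 1):r_end], na.rm = TRUE)
    prom <- min(wall_l, wall_r) - p[i]
    if (!is.finite(prom) || prom < min_prominence * rng) next
    sub <- 0
    if (i > 1 && i < n) {
      den <- p[i - 1] - 2 * p[i] + p[i + 1]
      if (den > 0) sub <- 0.5 * (p[i - 1] - p[i + 1]) / den
    }
    step <- if (i < n) pos[i + 1] - pos[i] else pos[i] - pos[i - 1]
    out <- c(out, pos[i] + sub * step)
  }
  sort(out)
}
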