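#' Generate synthetic cell tracks following a drift field
#'
#' Stand-in for nucleus tracking: each track starts at a uniform random
#' position in the domain and steps with the local drift velocity plus
#' isotropic Gaussian jitter. Output matches the track-table contract
#' (`track_id, frame, x_um, y_um`), frames strictly increasing.
#'
#' @param drift a [flow_spec] evaluated via [generate_flow_field()].
#' @param n_tracks number of tracks.
#' @param n_frames samples per track.
#' @param frame_interval_min minutes per frame.
#' @param jitter_sd isotropic positional jitter sd per step (um).
#' @param seed integer seed.
#' @param domain list with `width_um`, `height_um`.
#' @return data.frame `track_id, frame, x_um, y_um`.
#' @export
generate_tracks <- function(drift, n_tracks, n_frames, frame_interval_min = 10,
                            jitter_sd = 0, seed = 1,
                            domain = list(width_um = 200, height_um = 100)) {
  stopifnot(inherits(drift, "flow_spec"), n_tracks >= 1, n_frames >= 2)
  field <- generate_flow_field(drift, domain)
  with_seed(seed, {
    x <- stats::runif(n_tracks, 0, domain$width_um)
    y <- stats::runif(n_tracks, 0, domain$height_um)
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      out[[f]] <- data.frame(track_id = seq_len(n_tracks), frame = f,
                             x_um = x, y_um = y)
      v <- field(x, y, (f - 1) * frame_interval_min)
      x <- x + v$u * frame_interval_min + stats::rnorm(n_tracks, 0, jitter_sd)
      y <- y + v$v * frame_interval_min + stats::rnorm(n_tracks, 0, jitter_sd)
    }
    df <- do.call(rbind, out)
    df[order(df$track_id, df$frame), , drop = FALSE]
  })
}

#' Hertz force for a spherical indenter
#'
#' The contact law `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`
#' for a rigid sphere of radius `R` indenting an elastic half-space of
#' Young's modulus `E` and Poisson ratio `nu` to depth `delta`.
#'
#' @param delta_nm indentation depth (nm), >= 0.
#' @param E_pa Young's (effective) modulus in Pa.
#' @param model a [contact_model] giving `R_um` and `nu`.
#' @return force in nN.
#' @export
hertz_force <- function(delta_nm, E_pa, model = contact_model()) {
  delta_m <- pmax(delta_nm, 0) * 1e-9
  R_m <- model$R_um * 1e-6
  F_n <- (4 / 3) * (E_pa / (1 - model$nu^2)) * sqrt(R_m) * delta_m^1.5
  F_n * 1e9
}

#' Generate a synthetic AFM force curve
#'
#' Produces a `(z_nm, deflection_nm)` approach curve: flat (noise only)
#' before the contact point, Hertzian beyond it. Post-contact deflection d
#' solves `k * d = hertz(z - z_c - d)` so the curve is exactly the inverse
#' problem the fitting stage solves.
#'
#' @param E_true_pa ground-truth modulus (Pa).
#' @param model a [contact_model].
#' @param z_range_nm piezo travel, e.g. `c(0, 2000)`.
#' @param n_samples samples along the ramp.
#' @param contact_z_nm contact point position on the z axis.
#' @param noise_sd deflection noise sd (nm).
#' @param seed integer seed.
#' @return data.frame `z_nm, deflection_nm` of class `force_curve`.
#' @export
generate_force_curve <- function(E_true_pa, model = contact_model(),
                                 z_range_nm = c(0, 1500), n_samples = 300,
                                 contact_z_nm = 500, noise_sd = 0, seed = 1) {
  stopifnot(E_true_pa > 0, n_samples >= 10)
  z <- seq(z_range_nm[1], z_range_nm[2], length.out = n_samples)
  k <- model$k_nm   # nN/nm
  defl <- vapply(z, function(zi) {
    if (zi <= contact_z_nm) return(0)
    travel <- zi - contact_z_nm
    f <- function(d) k * d - hertz_force(travel - d, E_true_pa, model)
    stats::uniroot(f, c(0, travel), tol = 1e-12)$root
  }, numeric(1))
  if (noise_sd > 0)
    defl <- defl + with_seed(seed, stats::rnorm(n_samples, 0, noise_sd))
  structure(data.frame(z_nm = z, deflection_nm = defl),
            class = c("force_curve", "data.frame"),
            contact_z_nm = contact_z_nm, E_true_pa = E_true_pa)
}

#' Generate an elliptical outline point list
#'
#' Points on `x = a cos(theta), y = b sin(theta)` plus radial Gaussian
#' noise; if `a < b` the axes are swapped so `a >= b` always holds.
#'
#' @param a,b semi-axes (um).
#' @param n_points number of outline points.
#' @param noise_sd radial noise sd (um).
#' @param seed integer seed.
#' @param center optional `(x, y)` offset; `angle` rotates the outline.
#' @return data.frame `x_um, y_um`.
#' @export
generate_outline <- function(a, b, n_points = 200, noise_sd = 0, seed = 1,
                             center = c(0, 0), angle = 0) {
  stopifnot(a > 0, b > 0, n_points >= 6)
  if (a < b) { tmp <- a; a <- b; b <- tmp }
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  r_noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
             else rep(0, n_points)
  x0 <- a * cos(theta); y0 <- b * sin(theta)
  rr <- sqrt(x0^2 + y0^2)
  scale <- (rr + r_noise) / rr
  x0 <- x0 * scale; y0 <- y0 * scale
  data.frame(x_um = center[1] + x0 * cos(angle) - y0 * sin(angle),
             y_um = center[2] + x0 * sin(angle) + y0 * cos(angle))
}

#' Generate paired photobleach stripe profiles
#'
#' Baseline-normalised midline intensity profile with Gaussian bleach dips
#' at `stripe_centers_um`; the second-timepoint profile is the same pattern
#' displaced by `shift_um` (a vector recycles per stripe, permitting graded
#' shifts). Negative shifts move dips toward the head (x = 0).
#'
#' @param length_um profile extent (um), sampled every `sample_um`.
#' @param stripe_centers_um dip centers at t0 (um).
#' @param stripe_width_um full width at half maximum of each dip (um).
#' @param depth dip depth as a fraction of baseline (0-1).
#' @param noise_sd multiplicative noise sd (fraction of baseline).
#' @param shift_um per-stripe displacement applied at t1 (um; negative =
#'   head-ward).
#' @param seed integer seed.
#' @param sample_um sample spacing (um); default 0.108 emulates the
#'   lattice light-sheet pixel pitch.
#' @return list with `position_um`, `profile_t0`, `profile_t1`.
#' @export
generate_bleach_profile <- function(length_um = 320,
                                    stripe_centers_um = c(60, 110, 160, 210, 260),
                                    stripe_width_um = 20, depth = 0.5,
                                    noise_sd = 0, shift_um = 0, seed = 1,
                                    sample_um = 0.108) {
  pos <- seq(0, length_um, by = sample_um)
  sigma <- stripe_width_um / (2 * sqrt(2 * log(2)))
  dips <- function(centers) {
    prof <- rep(1, length(pos))
    for (c0 in centers)
      prof <- prof - depth * exp(-(pos - c0)^2 / (2 * sigma^2))
    prof
  }
  shifts <- rep_len(shift_um, length(stripe_centers_um))
  p0 <- dips(stripe_centers_um)
  p1 <- dips(stripe_centers_um + shifts)
  if (noise_sd > 0) {
    p0 <- p0 * (1 + with_seed(seed, stats::rnorm(length(pos), 0, noise_sd)))
    p1 <- p1 * (1 + with_seed(seed + 1L, stats::rnorm(length(pos), 0, noise_sd)))
  }
  list(position_um = pos, profile_t0 = p0, profile_t1 = p1)
}
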