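#' Spherical-tip contact model for AFM force spectroscopy
#'
#' Default geometry matches the instrument configuration: a 10-um silica
#' bead glued to the cantilever (tip radius 5 um), spring constant
#' 0.2 N/m calibrated by the thermal-noise method, a 3 nN approach
#' set point, a 230 nm target indentation depth for the Hertz fit, and an
#' incompressible-tissue Poisson ratio of 0.5.
#'
#' @param R_um tip sphere radius (um).
#' @param k_N_m cantilever spring constant (N/m).
#' @param nu Poisson ratio, in [0, 0.5].
#' @param target_depth_nm indentation depth over which the Hertz law is
#'   fitted (nm).
#' @param setpoint_nN approach force set point (nN).
#' @return object of class `contact_model`. `k_nm` holds the spring
#'   constant in nN/nm (numerically equal to N/m).
#' @export
contact_model <- function(R_um = 5, k_N_m = 0.2, nu = 0.5,
                          target_depth_nm = 230, setpoint_nN = 3) {
  stopifnot(R_um > 0, k_N_m > 0, nu >= 0, nu <= 0.5,
            target_depth_nm > 0, setpoint_nN > 0)
  structure(list(R_um = R_um, k_N_m = k_N_m, k_nm = k_N_m, nu = nu,
                 target_depth_nm = target_depth_nm,
                 setpoint_nN = setpoint_nN),
            class = "contact_model")
}

#' Convert a raw force curve to calibrated force-indentation samples
#'
#' `F = k * deflection`; `indentation = z-travel - deflection`, both
#' zeroed at the supplied or detected contact point. The default contact
#' detector takes the last sample at which the deflection is below a small
#' multiple of the pre-contact noise floor; the Hertz fit re-estimates the
#' contact point jointly with the modulus, so this stage only needs a
#' coarse zero.
#'
#' @param curve data.frame `z_nm, deflection_nm`.
#' @param model a [contact_model].
#' @param contact_z_nm optional known contact point; `NULL` to detect.
#' @return data.frame `delta_nm, force_nN` (post-contact samples),
#'   with attribute `contact_z_nm`.
#' @export
force_indentation <- function(curve, model = contact_model(),
                              contact_z_nm = NULL) {
  z <- curve$z_nm; d <- curve$deflection_nm
  if (all(d <= 0 + 1e-12)) stop_config("no contact detected: zero deflection throughout")
  # saturation guard: a hard plateau below the set point means the detector
  # clipped before the approach finished
  tail_d <- d[seq.int(max(1L, length(d) - 9L), length(d))]
  if (max(d) * model$k_nm < model$setpoint_nN * 0.99 &&
      max(d) > 0 && stats::sd(tail_d) == 0 && all(tail_d == max(d)))
    stop_config("deflection saturates before reaching the set point")
  if (is.null(contact_z_nm)) {
    noise <- stats::sd(d[seq_len(max(3L, floor(length(d) * 0.2)))])
    thr <- max(3 * noise, 1e-6 * max(d))
    below <- which(d <= thr)
    contact_z_nm <- if (length(below)) z[max(below)] else z[1]
  }
  post <- z >= contact_z_nm
  delta <- (z[post] - contact_z_nm) - (d[post] - 0)
  structure(data.frame(delta_nm = delta, force_nN = model$k_nm * d[post]),
            contact_z_nm = contact_z_nm)
}

#' Fit the spherical Hertz law to a force curve
#'
#' Estimates the contact point and the effective modulus from the
#' linearised form of the spherical Hertz law
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`: since `F^(2/3)` is
#' linear in the tip-sample position `z - deflection`, a straight-line fit
#' over the high-force part of the approach (deflection noise is relatively
#' smallest there) extrapolated to zero force gives the contact point; the
#' modulus is then the least-squares slope of `F` against `delta^(3/2)`
#' over `delta` in `[0, target_depth]`. A threshold-based coarse detection
#' is used as fallback when the regression is degenerate. Errors if the
#' curve never reaches the target depth; warns if the post-contact force
#' is non-monotone beyond the noise floor.
#'
#' @param curve data.frame `z_nm, deflection_nm` (a `force_curve`).
#' @param model a [contact_model].
#' @param force_window fraction range of the maximum force used for the
#'   contact-point extrapolation (default 0.3 to 1).
#' @return object of class `hertz_fit`: `E_pa`, `contact_z_nm`,
#'   `rms_nN`, `depth_range_nm`, `n_points`.
#' @export
fit_hertz <- function(curve, model = contact_model(),
                      force_window = c(0.3, 1)) {
  z <- curve$z_nm; d <- curve$deflection_nm
  if (all(d <= 1e-12)) stop_config("no contact detected: zero deflection throughout")
  k <- model$k_nm
  Fp <- k * d
  sel0 <- Fp >= force_window[1] * max(Fp) & Fp <= force_window[2] * max(Fp)
  zc <- if (sum(sel0) >= 5) {
    co <- stats::coef(stats::lm(Fp[sel0]^(2 / 3) ~ I(z[sel0] - d[sel0])))
    if (is.finite(co[2]) && co[2] > 0) -co[1] / co[2] else NA_real_
  } else NA_real_
  if (!is.finite(zc) || zc < min(z) || zc > max(z))
    zc <- attr(force_indentation(curve, model), "contact_z_nm")

  eval_zc <- function(zc) {
    post <- z > zc
    if (sum(post) < 5) return(NULL)
    delta <- (z[post] - zc) - d[post]
    Fq <- k * d[post]
    sel <- delta >= 0 & delta <= model$target_depth_nm
    if (sum(sel) < 5) return(NULL)
    if (max(delta[sel]) < 0.9 * model$target_depth_nm) return(NULL)
    x <- delta[sel]^1.5
    y <- Fq[sel]
    A <- sum(x * y) / sum(x * x)       # F = A * delta^(3/2), A in nN/nm^1.5
    if (!is.finite(A) || A <= 0) return(NULL)
    list(zc = zc, A = A, rms = sqrt(mean((y - A * x)^2)),
         range = range(delta[sel]), n = sum(sel))
  }
  best <- eval_zc(zc)
  if (is.null(best))
    stop_config("curve does not reach the target indentation depth (%g nm)",
                model$target_depth_nm)
  # A [nN/nm^1.5] -> SI: F[N] = A*1e-9/(1e-9)^1.5 * delta_m^1.5
  A_si <- best$A * 1e-9 / (1e-9)^1.5
  E <- 3 * A_si * (1 - model$nu^2) / (4 * sqrt(model$R_um * 1e-6))

  post <- z > best$zc
  Fp <- k * d[post]
  if (length(Fp) > 3) {
    drawdown <- max(cummax(Fp) - Fp)
    if (drawdown > max(6 * best$rms, 0.05 * max(Fp)))
      warning("post-contact force is non-monotone beyond the noise floor")
  }
  structure(list(E_pa = E, contact_z_nm = best$zc, rms_nN = best$rms,
                 depth_range_nm = best$range, n_points = best$n),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("hertz_fit: E = %.1f Pa (contact %.1f nm, rms %.3g nN, %d pts)\n",
              x$E_pa, x$contact_z_nm, x$rms_nN, x$n_points))
  invisible(x)
}
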