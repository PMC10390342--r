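#' Generate a synthetic VNC condensation scene
#'
#' Emulates the two-phase condensation of the embryonic ventral nerve cord
#' under the elliptical-cylinder idealisation:
#' \itemize{
#'   \item Phase 1 (anisotropic, default 0-180 min): the length shrinks by
#'     `phase1_length_drop`, while width and height grow by the common
#'     factor `sqrt(L0 / L(t))` so the cylinder volume
#'     `pi (W/2)(H/2) L` is exactly conserved (isovolumetric remodeling).
#'   \item Phase 2 (isotropic, default 180-720 min): all three dimensions
#'     shrink linearly, with net volume loss.
#' }
#' Collagen-IV intensity rises exponentially (`I0 exp(k t)`) until
#' `saturation_t_min`, then holds. Tail displacement follows a logistic
#' ramp whose time constant equals `1/k`, so the early condensation rate is
#' proportional to intensity and peaks at `ramp_mid_min` (inside phase 1).
#'
#' @param L0,W0,H0 initial length/width/height (um).
#' @param phase1_end_min,phase2_end_min phase boundaries (min).
#' @param dt_min sampling interval (min; native resolution 2 min).
#' @param phase1_length_drop fractional length decrease over phase 1.
#' @param phase2_dim_drop fractional decrease of each dimension in phase 2.
#' @param intensity_rate exponential induction rate k (1/min).
#' @param saturation_t_min time at which intensity saturates (min).
#' @param ramp_max_um,ramp_mid_min logistic tail-displacement amplitude and
#'   midpoint.
#' @param noise_sd observation noise (fraction): multiplicative on
#'   intensity, and multiplicative on the frame-to-frame displacement
#'   increments (tail-motion noise scales with how fast the tail moves;
#'   increments stay positive at realistic levels, so the observed
#'   displacement remains non-decreasing).
#' @param seed integer seed.
#' @return list of class `condensation_scene` with `times_min`, `dims`
#'   (data.frame `L_um, W_um, H_um`), `col4_intensity`,
#'   `tail_displacement_um`, `phase_boundaries_min` and the ground-truth
#'   parameters.
#' @export
generate_condensation_scene <- function(L0 = 220, W0 = 40, H0 = 30,
                                        phase1_end_min = 180,
                                        phase2_end_min = 720,
                                        dt_min = 2,
                                        phase1_length_drop = 0.30,
                                        phase2_dim_drop = 0.10,
                                        intensity_rate = log(10) / 180,
                                        saturation_t_min = 300,
                                        ramp_max_um = 60,
                                        ramp_mid_min = 175,
                                        noise_sd = 0, seed = 1) {
  stopifnot(L0 > 0, W0 > 0, H0 > 0, phase1_end_min > 0,
            phase2_end_min > phase1_end_min,
            phase1_length_drop > 0, phase1_length_drop < 1)
  times <- seq(0, phase2_end_min, by = dt_min)
  t1 <- phase1_end_min

  L <- ifelse(times <= t1,
              L0 * (1 - phase1_length_drop * times / t1),
              L0 * (1 - phase1_length_drop) *
                (1 - phase2_dim_drop * (times - t1) / (phase2_end_min - t1)))
  grow <- sqrt(L0 / pmin(L, L0 * 1))       # phase-1 isovolumetric factor
  grow1 <- sqrt(L0 / (L0 * (1 - phase1_length_drop)))
  W <- ifelse(times <= t1, W0 * grow,
              W0 * grow1 *
                (1 - phase2_dim_drop * (times - t1) / (phase2_end_min - t1)))
  H <- ifelse(times <= t1, H0 * grow,
              H0 * grow1 *
                (1 - phase2_dim_drop * (times - t1) / (phase2_end_min - t1)))

  intensity <- exp(intensity_rate * pmin(times, saturation_t_min))
  tau <- 1 / intensity_rate
  ramp <- function(t) ramp_max_um / (1 + exp(-(t - ramp_mid_min) / tau))
  displacement <- ramp(times) - ramp(0)

  if (noise_sd > 0) {
    obs <- with_seed(seed, {
      inc <- diff(displacement)
      list(i = intensity * (1 + stats::rnorm(length(times), 0, noise_sd)),
           d = c(0, cumsum(inc * (1 + stats::rnorm(length(inc), 0,
                                                   noise_sd)))))
    })
    intensity <- obs$i
    displacement <- obs$d
  }

  structure(list(times_min = times,
                 dims = data.frame(L_um = L, W_um = W, H_um = H),
                 col4_intensity = intensity,
                 tail_displacement_um = displacement,
                 phase_boundaries_min = c(phase1_end_min, phase2_end_min),
                 params = list(L0 = L0, W0 = W0, H0 = H0,
                               intensity_rate = intensity_rate,
                               ramp_mid_min = ramp_mid_min,
                               ramp_max_um = ramp_max_um,
                               noise_sd = noise_sd, seed = seed)),
            class = "condensation_scene")
}
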