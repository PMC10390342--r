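#' Build the two-material core-plus-shell tissue model
#'
#' Idealises the nerve cord as a soft elastic core shaped as a capped
#' elliptical cylinder (length `L`, elliptical cross-section `W` x `H`),
#' wrapped in a thin basement-membrane shell that loads the core either as
#' a normal surface pressure or as a membrane prestress (surface tension)
#' with independent axial and circumferential components. The head cap is
#' fully displacement-fixed, representing attachment to the brain. The
#' core is discretised with trilinear hexahedra (mean-dilatation
#' formulation, stable at the near-incompressible default Poisson ratio);
#' the shell enters as equivalent surface tractions of a prestressed
#' membrane layer on the boundary faces, so curvature effects and local
#' tension perturbations (stripes) are captured without meshing the shell.
#'
#' All claims drawn from this model are sign and ordering patterns of the
#' deformation, not magnitudes; material constants and load levels are
#' free parameters chosen to keep strains moderate.
#'
#' @param L,W,H geometry (um).
#' @param E_core_pa core Young's modulus (Pa).
#' @param nu_core core Poisson ratio (near-incompressible default 0.49).
#' @param sigma_ax,sigma_circ membrane tension components (N/m) used by
#'   the tension load cases.
#' @param pressure_pa normal pressure (Pa) used by the pressure load case.
#' @param stripe optional list `(center_um, width_um, scale)` reducing the
#'   membrane tension to `scale` times its value on lateral faces within
#'   the stripe.
#' @param nx,nc axial and cross-section mesh divisions (use even values so
#'   the mid-length plane and mid-axes fall on mesh nodes).
#' @return object of class `shell_model` with the mesh, the assembled and
#'   factorised core stiffness, and the load parameters.
#' @export
build_shell_model <- function(L = 200, W = 40, H = 24,
                              E_core_pa = 100, nu_core = 0.49,
                              sigma_ax = 1e-4, sigma_circ = 1e-5,
                              pressure_pa = 10,
                              stripe = NULL, nx = 16, nc = 6) {
  stopifnot(L > 0, W > 0, H > 0, E_core_pa > 0,
            nu_core >= 0, nu_core < 0.5,
            sigma_ax >= 0, sigma_circ >= 0, pressure_pa >= 0)
  if (nx %% 2 == 1 || nc %% 2 == 1)
    stop_config("nx and nc must be even so mid-planes fall on mesh nodes")
  if (!is.null(stripe)) {
    stopifnot(stripe$scale >= 0, stripe$scale <= 1)
    if (stripe$width_um < L / nx)
      stop_config("mesh too coarse for the stripe width (%g um < element %g um)",
                  stripe$width_um, L / nx)
  }
  mesh <- fem_mesh_cylinder(L, W, H, nx = nx, nc = nc, section = "ellipse")
  if (fem_min_detJ(mesh) <= 0) stop_config("mesh contains inverted elements")
  E_int <- E_core_pa * 1e-3            # Pa -> nN/um^2
  K <- fem_stiffness(mesh, E_int, nu_core)
  fixed <- as.vector(rbind(3 * mesh$head_nodes - 2,
                           3 * mesh$head_nodes - 1, 3 * mesh$head_nodes))
  structure(list(mesh = mesh, K = K, fixed_dofs = fixed,
                 E_core_pa = E_core_pa, nu_core = nu_core,
                 sigma_ax = sigma_ax, sigma_circ = sigma_circ,
                 pressure_pa = pressure_pa, stripe = stripe),
            class = "shell_model")
}

# membrane tension function (internal units nN/um) honouring the stripe
model_sigma_fun <- function(model, sigma_ax, sigma_circ, stripe = model$stripe) {
  s_ax <- sigma_ax * 1e3               # N/m -> nN/um
  s_ci <- sigma_circ * 1e3
  function(centroid, label) {
    sc <- 1
    if (!is.null(stripe) && label == "lateral" &&
        abs(centroid[1] - stripe$center_um) <= stripe$width_um / 2)
      sc <- stripe$scale
    c(s_ax * sc, s_ci * sc)
  }
}

#' Simulate static equilibrium of the core under a shell load case
#'
#' Load cases:
#' \describe{
#'   \item{`normal_pressure`}{uniform pressure on the free surface
#'     (lateral wall and tail cap), directed inward.}
#'   \item{`isotropic_tension`}{membrane prestress with equal axial and
#'     circumferential components `sigma_ax = sigma_circ`.}
#'   \item{`anisotropic_tension`}{membrane prestress with the supplied
#'     (typically axially dominated) components.}
#' }
#' `load_scale` multiplies the load; in this small-strain linear model the
#' displacement field scales exactly with it, so sign patterns are
#' load-sweep-robust by construction.
#'
#' @param model a [build_shell_model()] result.
#' @param load_case one of the cases above.
#' @param load_scale multiplier on the configured load magnitude.
#' @param use_stripe apply the model's stripe tension reduction (tension
#'   cases only).
#' @return object of class `deformation_result`: signed `dL_um`, `dW_um`,
#'   `dH_um` at the mid-length section, `tail_displacement_um` (positive =
#'   head-ward), `volume_change_rel`, mid-section `eccentricity` before
#'   and after, and the nodal displacement matrix `u_um`.
#' @export
simulate_shell <- function(model,
                           load_case = c("normal_pressure",
                                         "isotropic_tension",
                                         "anisotropic_tension"),
                           load_scale = 1, use_stripe = TRUE) {
  stopifnot(inherits(model, "shell_model"))
  load_case <- match.arg(load_case)
  mesh <- model$mesh
  stripe <- if (use_stripe) model$stripe else NULL
  f <- switch(load_case,
    normal_pressure = fem_load_pressure(mesh,
                                        model$pressure_pa * 1e-3 * load_scale),
    isotropic_tension = fem_load_membrane(
      mesh, model_sigma_fun(model, model$sigma_ax * load_scale,
                            model$sigma_ax * load_scale, stripe)),
    anisotropic_tension = fem_load_membrane(
      mesh, model_sigma_fun(model, model$sigma_ax * load_scale,
                            model$sigma_circ * load_scale, stripe)))
  u <- fem_solve(model$K, f, model$fixed_dofs)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  colnames(U) <- c("ux", "uy", "uz")

  nodes <- mesh$nodes
  L <- mesh$L
  tail_ux <- mean(U[mesh$tail_nodes, "ux"])

  # mid-length cross-section nodes
  mid <- which(abs(nodes[, "x"] - L / 2) < 1e-9)
  tol <- 1e-9
  iyp <- mid[which.max(nodes[mid, "y"])]
  iym <- mid[which.min(nodes[mid, "y"])]
  izp <- mid[which.max(nodes[mid, "z"])]
  izm <- mid[which.min(nodes[mid, "z"])]
  dW <- U[iyp, "uy"] - U[iym, "uy"]
  dH <- U[izp, "uz"] - U[izm, "uz"]

  # mid-section boundary ring for eccentricity
  r2 <- (nodes[mid, "y"] / (mesh$W / 2))^2 + (nodes[mid, "z"] / (mesh$H / 2))^2
  ring <- mid[r2 > 1 - 1e-6]
  ecc0 <- fit_ellipse(cbind(nodes[ring, "y"], nodes[ring, "z"]))$eccentricity
  ecc1 <- fit_ellipse(cbind(nodes[ring, "y"] + U[ring, "uy"],
                            nodes[ring, "z"] + U[ring, "uz"]))$eccentricity

  v0 <- fem_volume(mesh)
  v1 <- fem_volume(mesh, u)

  structure(list(load_case = load_case, load_scale = load_scale,
                 dL_um = tail_ux, dW_um = dW, dH_um = dH,
                 tail_displacement_um = -tail_ux,
                 volume_change_rel = (v1 - v0) / v0,
                 eccentricity_before = ecc0, eccentricity_after = ecc1,
                 u_um = U),
            class = "deformation_result")
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf(paste0("deformation_result (%s, scale %.3g): dL=%.4g dW=%.4g ",
                     "dH=%.4g um; tail %.4g um head-ward; dV/V=%.3g; ",
                     "ecc %.3f -> %.3f\n"),
              x$load_case, x$load_scale, x$dL_um, x$dW_um, x$dH_um,
              x$tail_displacement_um, x$volume_change_rel,
              x$eccentricity_before, x$eccentricity_after))
  invisible(x)
}

#' Compare condensation with and without a local tension reduction
#'
#' Runs the requested tension load case with the model's stripe
#' perturbation disabled and enabled (tension scaled by `scale` inside the
#' stripe) and reports the tail displacement of both, quantifying the
#' long-range effect of a local surface-tension defect.
#'
#' @param model a [build_shell_model()] result (must carry a `stripe`).
#' @param load_case tension load case to perturb.
#' @param scale overrides the stripe's tension scale factor if given.
#' @return list with `base`, `perturbed` (both `deformation_result`) and
#'   `tail_ratio` = perturbed / base tail displacement.
#' @export
stripe_perturbation <- function(model, load_case = "anisotropic_tension",
                                scale = NULL) {
  stopifnot(inherits(model, "shell_model"))
  if (is.null(model$stripe)) stop_config("model has no stripe configured")
  if (!is.null(scale)) model$stripe$scale <- scale
  base <- simulate_shell(model, load_case, use_stripe = FALSE)
  pert <- simulate_shell(model, load_case, use_stripe = TRUE)
  list(base = base, perturbed = pert,
       tail_ratio = pert$tail_displacement_um / base$tail_displacement_um)
}
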