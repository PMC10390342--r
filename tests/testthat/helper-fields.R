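# Shared fixture builders (all generated in code, no stored data).

# field series with every vector equal to (u0, v0)
uniform_field <- function(u0 = 1, v0 = 0, nx = 11, ny = 7, nt = 3,
                          spacing = 2) {
  field_series(x_um = (seq_len(nx) - 1) * spacing,
               y_um = (seq_len(ny) - 1) * spacing,
               u = array(u0, c(ny, nx, nt)),
               v = array(v0, c(ny, nx, nt)))
}

# field of unit vectors with iid uniform random orientations
random_orientation_field <- function(n = 40, spacing = 2, nt = 1, seed = 1) {
  th <- vncmorph:::with_seed(seed,
          array(stats::runif(n * n * nt) * 2 * pi, c(n, n, nt)))
  field_series(x_um = (seq_len(n) - 1) * spacing,
               y_um = (seq_len(n) - 1) * spacing,
               u = cos(th), v = sin(th))
}

# speckle stack advected by a uniform integer-pixel shift
shifted_speckle_stack <- function(shift_px = 3, pixel_size_um = 0.5,
                                  shape = c(128, 128), n_frames = 2,
                                  seed = 11, noise_sd = 0) {
  speed <- shift_px * pixel_size_um   # um per frame at 1 min/frame
  flow <- generate_flow_field(
    flow_spec("uniform", peak_speed = speed, axis = c(1, 0)),
    list(width_um = shape[2] * pixel_size_um,
         height_um = shape[1] * pixel_size_um))
  render_speckle_stack(flow, speckle_params(
    image_shape = shape, pixel_size_um = pixel_size_um,
    frame_interval_min = 1, n_frames = n_frames,
    noise_sd = noise_sd, seed = seed))
}

# deflection (nm) at the target Hertz-fit depth: the force scale the fit uses
deflection_at_target <- function(E_pa, model = contact_model()) {
  hertz_force(model$target_depth_nm, E_pa, model) / model$k_nm
}

# regular polygon approximating a circle
circle_polygon <- function(r, n = 60, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}
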