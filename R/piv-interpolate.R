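#' Spatiotemporal interpolation kernel
#'
#' Truncated-Gaussian kernel for smoothing a displacement field series in
#' space and time. `size` is the full truncation width (contributions
#' beyond `size/2` from the target are ignored); `sigma` the Gaussian
#' standard deviation. Temporal quantities may be given in frames or
#' minutes; set `temporal_unit` accordingly.
#'
#' @param spatial_size,spatial_sigma spatial truncation width and sigma (um).
#' @param temporal_size,temporal_sigma temporal truncation width and sigma.
#' @param temporal_unit `"min"` or `"frames"`.
#' @return object of class `interpolation_kernel`.
#' @export
interpolation_kernel <- function(spatial_size = 50, spatial_sigma = 10,
                                 temporal_size = 90, temporal_sigma = 40,
                                 temporal_unit = c("min", "frames")) {
  temporal_unit <- match.arg(temporal_unit)
  stopifnot(spatial_sigma > 0, spatial_size >= spatial_sigma,
            temporal_sigma > 0, temporal_size >= temporal_sigma)
  structure(list(spatial_size = spatial_size, spatial_sigma = spatial_sigma,
                 temporal_size = temporal_size, temporal_sigma = temporal_sigma,
                 temporal_unit = temporal_unit),
            class = "interpolation_kernel")
}

#' Named interpolation kernel presets
#'
#' `"whole_tissue"`: spatial 50 um (sigma 10 um), temporal 90 min (sigma
#' 40 min), used for whole-tissue confocal and MOSAIC fields;
#' `"hires"`: spatial 10 um (sigma 2 um), temporal 5 frames (sigma 2
#' frames), used for the high-resolution partial fields.
#'
#' @param name preset name.
#' @return an [interpolation_kernel].
#' @export
kernel_preset <- function(name = c("whole_tissue", "hires")) {
  name <- match.arg(name)
  switch(name,
    whole_tissue = interpolation_kernel(50, 10, 90, 40, "min"),
    hires = interpolation_kernel(10, 2, 5, 2, "frames"))
}

#' Interpolate a displacement field series in space and time
#'
#' Each output vector is the Gaussian-weighted mean of the valid input
#' vectors lying within the truncation window in both space and time;
#' weights are normalised over the contributing (valid) vectors only, so
#' the result is a convex combination of valid neighbours. Nodes with no
#' valid contributor anywhere in their window remain invalid.
#'
#' @param fields a `piv_field_series`.
#' @param kernel an [interpolation_kernel] (or preset name).
#' @return an interpolated `piv_field_series` on the same grid.
#' @export
interpolate_field_series <- function(fields, kernel = kernel_preset("whole_tissue")) {
  stopifnot(inherits(fields, "piv_field_series"))
  if (is.character(kernel)) kernel <- kernel_preset(kernel)
  stopifnot(inherits(kernel, "interpolation_kernel"))
  if (kernel$spatial_size < fields$grid_size_um)
    warning("spatial kernel smaller than grid spacing: effectively nearest-neighbour")

  dt <- if (kernel$temporal_unit == "min") fields$frame_interval_min else 1
  t_half <- kernel$temporal_size / 2 / dt          # frames
  t_sigma <- kernel$temporal_sigma / dt            # frames
  s_half <- kernel$spatial_size / 2
  s_sigma <- kernel$spatial_sigma

  d <- dim(fields$u)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  X <- matrix(rep(fields$x_um, each = ny), ny, nx)
  Y <- matrix(rep(fields$y_um, times = nx), ny, nx)

  u_out <- v_out <- array(NA_real_, d)
  valid_out <- array(FALSE, d)

  # spatial weight matrix between all grid nodes (ny*nx x ny*nx), truncated
  pos <- cbind(as.vector(X), as.vector(Y))
  d2 <- outer(pos[, 1], pos[, 1], "-")^2 + outer(pos[, 2], pos[, 2], "-")^2
  Ws <- exp(-d2 / (2 * s_sigma^2))
  Ws[sqrt(d2) > s_half] <- 0

  for (t in seq_len(nt)) {
    t_in <- which(abs(seq_len(nt) - t) <= t_half)
    wt <- exp(-((t_in - t) * 1)^2 / (2 * t_sigma^2))
    num_u <- num_v <- den <- numeric(ny * nx)
    for (j in seq_along(t_in)) {
      tt <- t_in[j]
      ok <- as.vector(fields$valid[, , tt])
      if (!any(ok)) next
      uu <- as.vector(fields$u[, , tt])[ok]
      vv <- as.vector(fields$v[, , tt])[ok]
      Wsub <- Ws[, ok, drop = FALSE] * wt[j]
      num_u <- num_u + as.vector(Wsub %*% uu)
      num_v <- num_v + as.vector(Wsub %*% vv)
      den <- den + rowSums(Wsub)
    }
    has <- den > 0
    u_t <- v_t <- rep(NA_real_, ny * nx)
    u_t[has] <- num_u[has] / den[has]
    v_t[has] <- num_v[has] / den[has]
    u_out[, , t] <- matrix(u_t, ny, nx)
    v_out[, , t] <- matrix(v_t, ny, nx)
    valid_out[, , t] <- matrix(has, ny, nx)
  }

  out <- fields
  out$u <- u_out; out$v <- v_out; out$valid <- valid_out
  out$corr <- array(NA_real_, d)
  out$interpolated <- TRUE
  out$kernel <- kernel
  out
}

#' Sample an interpolated field at arbitrary points
#'
#' Bilinear sampling of the (u, v) components of one frame of a field
#' series at physical positions; invalid nodes propagate as NA.
#'
#' @param fields a `piv_field_series`.
#' @param x_um,y_um query positions (um).
#' @param frame frame-pair index.
#' @return list `u`, `v` (um/frame).
#' @export
sample_field <- function(fields, x_um, y_um, frame = 1L) {
  gx <- fields$x_um; gy <- fields$y_um
  u <- fields$u[, , frame]; v <- fields$v[, , frame]
  interp1 <- function(g, q) {
    i <- findInterval(q, g, all.inside = TRUE)
    f <- (q - g[i]) / (g[i + 1] - g[i])
    list(i = i, f = pmin(pmax(f, 0), 1))
  }
  ix <- interp1(gx, x_um); iy <- interp1(gy, y_um)
  gv <- function(M) {
    M[cbind(iy$i, ix$i)] * (1 - iy$f) * (1 - ix$f) +
      M[cbind(iy$i + 1, ix$i)] * iy$f * (1 - ix$f) +
      M[cbind(iy$i, ix$i + 1)] * (1 - iy$f) * ix$f +
      M[cbind(iy$i + 1, ix$i + 1)] * iy$f * ix$f
  }
  list(u = gv(u), v = gv(v))
}
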