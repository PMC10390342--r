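#' Kymograph of a displacement field series
#'
#' Averages the velocity magnitude (or its x component) over all valid
#' vectors in each anteroposterior-axis bin, per frame, yielding a
#' position-by-time matrix. Bins with no valid vector are `NA` (missing),
#' never zero. Values are reported in um/min using the frame interval.
#'
#' @param fields a `piv_field_series`.
#' @param mode `"speed"` (vector magnitude) or `"x_component"`.
#' @return object of class `kymograph`: list with `position_um` (AP bin
#'   centres), `frames`, and `values` matrix `[n_positions, n_frames]`.
#' @export
kymograph <- function(fields, mode = c("speed", "x_component")) {
  stopifnot(inherits(fields, "piv_field_series"))
  mode <- match.arg(mode)
  d <- dim(fields$u)
  if (d[3] < 1) stop_config("empty field series")
  per_min <- 1 / fields$frame_interval_min
  vals <- matrix(NA_real_, d[2], d[3])
  for (t in seq_len(d[3])) {
    u <- fields$u[, , t]; v <- fields$v[, , t]
    m <- if (mode == "speed") sqrt(u^2 + v^2) else u
    m[!fields$valid[, , t]] <- NA
    vals[, t] <- colMeans(m, na.rm = TRUE) * per_min
  }
  vals[is.nan(vals)] <- NA_real_
  structure(list(position_um = fields$x_um, frames = seq_len(d[3]),
                 values = vals, mode = mode),
            class = "kymograph")
}

# mean |cos| or signed cos of angles between vector (u0,v0) and vectors
# (u,v); zero-length vectors must be excluded by the caller
cos_angles <- function(u0, v0, u, v, signed = FALSE) {
  cc <- (u0 * u + v0 * v) / (sqrt(u0^2 + v0^2) * sqrt(u^2 + v^2))
  cc <- pmin(pmax(cc, -1), 1)
  if (signed) cc else abs(cc)
}

#' Local alignment coherence of a displacement field series
#'
#' Per frame, `n_samples` reference locations are drawn among the valid
#' non-zero vectors of the raw (non-interpolated) field; each reference's
#' orientation is compared to every other valid vector within
#' `radius_um` by the norm (absolute value) of the cosine of the angle
#' between them, averaged per reference, then over references. The frame
#' series is finally smoothed with a centred walking average over
#' `smooth_frames` frames. Values near 1 indicate coherent local motion.
#'
#' References are sampled uniformly without replacement when enough valid
#' vectors exist, with replacement otherwise; the reference itself is
#' excluded from its neighbourhood. A reference with no neighbour
#' contributes nothing; a frame with no contributing reference is `NA`.
#'
#' @param fields a raw `piv_field_series`.
#' @param n_samples reference locations per frame (default 256).
#' @param radius_um neighbourhood radius (default 8 um).
#' @param smooth_frames walking-average window (default 5 frames).
#' @param seed integer seed for reference sampling.
#' @return object of class `coherence_series`: list with `frames`, `value`
#'   (smoothed), `raw`, and metadata.
#' @export
local_alignment_coherence <- function(fields, n_samples = 256, radius_um = 8,
                                      smooth_frames = 5, seed = 1) {
  stopifnot(inherits(fields, "piv_field_series"))
  if (isTRUE(fields$interpolated))
    warning("local alignment coherence is defined on the non-interpolated field")
  d <- dim(fields$u)
  ny <- d[1]; nx <- d[2]
  X <- as.vector(matrix(rep(fields$x_um, each = ny), ny, nx))
  Y <- as.vector(matrix(rep(fields$y_um, times = nx), ny, nx))
  raw <- with_seed(seed, {
    vapply(seq_len(d[3]), function(t) {
      u <- as.vector(fields$u[, , t]); v <- as.vector(fields$v[, , t])
      ok <- as.vector(fields$valid[, , t]) & is.finite(u) & is.finite(v) &
        (u^2 + v^2) > 0
      idx <- which(ok)
      if (length(idx) == 0L) return(NA_real_)
      refs <- if (length(idx) >= n_samples) sample(idx, n_samples)
              else sample(idx, n_samples, replace = TRUE)
      per_ref <- vapply(refs, function(i) {
        nb <- idx[idx != i &
                    (X[idx] - X[i])^2 + (Y[idx] - Y[i])^2 <= radius_um^2]
        if (length(nb) == 0L) return(NA_real_)
        mean(cos_angles(u[i], v[i], u[nb], v[nb]))
      }, numeric(1))
      if (all(is.na(per_ref))) NA_real_ else mean(per_ref, na.rm = TRUE)
    }, numeric(1))
  })
  structure(list(frames = seq_len(d[3]),
                 value = moving_average(raw, smooth_frames), raw = raw,
                 smooth_frames = smooth_frames, radius_um = radius_um,
                 n_samples = n_samples, variant = "norm"),
            class = "coherence_series")
}

#' Directional coherence against a reference axis
#'
#' Samples an `grid_n` x `grid_n` lattice of vectors at `grid_spacing_um`
#' from the interpolated field (centred on `roi_center_um`, or the field
#' centre) and computes, per frame, the mean signed cosine of the angle
#' between each sampled vector and the tail-to-head reference direction.
#' Values near 1 indicate motion along the reference axis; zero-length or
#' invalid samples are excluded, and an all-excluded frame is `NA`.
#'
#' @param fields an interpolated `piv_field_series`.
#' @param reference_axis unit 2-vector, tail-to-head direction.
#' @param grid_n lattice side (default 11).
#' @param grid_spacing_um lattice spacing (default 3 um).
#' @param roi_center_um optional `(x, y)` centre of the lattice.
#' @return a `coherence_series` (signed variant, in [-1, 1]).
#' @export
directional_coherence <- function(fields, reference_axis = c(-1, 0),
                                  grid_n = 11, grid_spacing_um = 3,
                                  roi_center_um = NULL) {
  stopifnot(inherits(fields, "piv_field_series"), length(reference_axis) == 2L)
  ax <- reference_axis / sqrt(sum(reference_axis^2))
  if (is.null(roi_center_um))
    roi_center_um <- c(mean(range(fields$x_um)), mean(range(fields$y_um)))
  offs <- (seq_len(grid_n) - (grid_n + 1) / 2) * grid_spacing_um
  qx <- rep(roi_center_um[1] + offs, times = grid_n)
  qy <- rep(roi_center_um[2] + offs, each = grid_n)
  if (min(qx) < min(fields$x_um) || max(qx) > max(fields$x_um) ||
      min(qy) < min(fields$y_um) || max(qy) > max(fields$y_um))
    stop_config("sampling lattice does not fit inside the field extent")
  d <- dim(fields$u)
  val <- vapply(seq_len(d[3]), function(t) {
    s <- sample_field(fields, qx, qy, t)
    mag <- sqrt(s$u^2 + s$v^2)
    ok <- is.finite(mag) & mag > 0
    if (!any(ok)) return(NA_real_)
    mean(cos_angles(ax[1], ax[2], s$u[ok], s$v[ok], signed = TRUE))
  }, numeric(1))
  structure(list(frames = seq_len(d[3]), value = val, raw = val,
                 smooth_frames = 1, reference_axis = ax, variant = "signed"),
            class = "coherence_series")
}
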