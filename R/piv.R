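#' PIV correlation parameters
#'
#' Window sizes are physical (um) and are converted to odd pixel counts at
#' the stack's pixel size, so the same preset applies across imaging
#' modalities. The source window in frame t is matched against the larger
#' search window in frame t+1 by zero-mean normalised cross-correlation
#' (correlation coefficient), so `corr_threshold` lives on the usual
#' [0, 1] scale.
#'
#' @param source_size source window size (um).
#' @param search_size search window size (um); must exceed `source_size`.
#' @param grid_size grid node spacing (um).
#' @param corr_threshold minimum peak correlation for a vector to be valid.
#' @param modality_label free-text label.
#' @return object of class `piv_params`.
#' @export
piv_params <- function(source_size, search_size, grid_size,
                       corr_threshold = 0.5, modality_label = "custom") {
  stopifnot(source_size > 0, search_size > source_size, grid_size > 0,
            corr_threshold >= 0, corr_threshold <= 1)
  structure(list(source_size = source_size, search_size = search_size,
                 grid_size = grid_size, corr_threshold = corr_threshold,
                 modality_label = modality_label),
            class = "piv_params")
}

#' Named PIV parameter presets
#'
#' The three optimised acquisition presets: whole-tissue confocal
#' (source 9 um, search 16 um, grid 5 um, threshold 0.5), high-resolution
#' partial-field confocal (2/4/1 um, threshold 0.3) and whole-tissue
#' lattice light-sheet/MOSAIC (5/10/3 um, threshold 0.5).
#'
#' @param name `"confocal_whole"`, `"confocal_hires"` or `"mosaic"`.
#' @return a [piv_params].
#' @export
piv_preset <- function(name = c("confocal_whole", "confocal_hires", "mosaic")) {
  name <- match.arg(name)
  switch(name,
    confocal_whole = piv_params(9, 16, 5, 0.5, "confocal_whole"),
    confocal_hires = piv_params(2, 4, 1, 0.3, "confocal_hires"),
    mosaic         = piv_params(5, 10, 3, 0.5, "mosaic"))
}

# 3-point sub-pixel peak refinement along one axis. Gaussian fit when all
# three correlations are positive, parabolic otherwise; returns offset in
# (-1, 1) px (0 if degenerate).
subpixel_offset <- function(cm, cz, cp) {
  if (cm > 0 && cz > 0 && cp > 0) {
    den <- 2 * (log(cm) + log(cp) - 2 * log(cz))
    if (den < 0) return(max(-0.5, min(0.5, (log(cm) - log(cp)) / den)))
  }
  den <- 2 * (cm + cp - 2 * cz)
  if (den < 0) return(max(-0.5, min(0.5, (cm - cp) / den)))
  0
}

#' Compute a PIV displacement field series
#'
#' For every node of a regular grid and every consecutive frame pair, the
#' source window centred at the node in frame t is cross-correlated
#' (zero-mean, normalised) against the search window in frame t+1; the
#' correlation peak, refined per axis by a 3-point Gaussian fit, gives the
#' displacement. Vectors with peak correlation below `corr_threshold`, with
#' zero-variance windows, or whose source window leaves the ROI are flagged
#' invalid. Ties between equal peaks are broken toward the smaller
#' displacement.
#'
#' @param stack an [image_stack] with at least two frames.
#' @param params a [piv_params] (or preset name string).
#' @param roi_mask optional logical matrix `[H, W]`; a vector is valid only
#'   if its entire source window lies inside the ROI.
#' @return object of class `piv_field_series`: list with grid coordinates
#'   `x_um`, `y_um`, arrays `u`, `v` (um/frame), `corr`, `valid` of shape
#'   `[ny, nx, n_pairs]`, plus `frame_interval_min`, `grid_size_um` and the
#'   parameters used.
#' @export
compute_piv <- function(stack, params, roi_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(params)) params <- piv_preset(params)
  stopifnot(inherits(params, "piv_params"))
  d <- dim(stack$data)
  if (d[3] < 2) stop_config("PIV needs at least 2 frames")
  ps <- stack$pixel_size_um

  src_px <- um_to_odd_px(params$source_size, ps)
  sea_px <- um_to_odd_px(params$search_size, ps)
  if (sea_px <= src_px) sea_px <- src_px + 2
  grid_px <- max(1L, round(params$grid_size / ps))
  if (sea_px > min(d[1], d[2]))
    stop_config("search window (%d px) larger than image (%d x %d)",
                sea_px, d[1], d[2])

  hs <- (src_px - 1L) %/% 2L   # source half-width
  hb <- (sea_px - 1L) %/% 2L   # search half-width
  m <- hb - hs                 # max displacement (px) each direction

  # grid node pixel centres (1-based), source+search windows fully inside
  r_nodes <- seq(hb + 1L, d[1] - hb, by = grid_px)
  c_nodes <- seq(hb + 1L, d[2] - hb, by = grid_px)
  ny <- length(r_nodes); nx <- length(c_nodes)
  if (ny < 1 || nx < 1)
    stop_config("image too small for grid with this search window")

  n_off <- 2L * m + 1L
  # linear index offsets of an src_px x src_px patch within a column-major
  # image of height d[1], and of the candidate displacement lags
  patch_off <- as.vector(outer(-hs:hs, (-hs:hs) * d[1], "+"))
  lag_off <- as.vector(outer(-m:m, (-m:m) * d[1], "+"))
  lag_dy <- rep(-m:m, times = n_off)   # row displacement per lag
  lag_dx <- rep(-m:m, each = n_off)    # col displacement per lag
  npx <- src_px^2

  n_pairs <- d[3] - 1L
  u <- v <- corr <- array(NA_real_, c(ny, nx, n_pairs))
  valid <- array(FALSE, c(ny, nx, n_pairs))

  roi_ok <- function(r, c) {
    if (is.null(roi_mask)) return(TRUE)
    all(roi_mask[(r - hs):(r + hs), (c - hs):(c + hs)])
  }

  for (t in seq_len(n_pairs)) {
    f0 <- stack$data[, , t]
    f1 <- stack$data[, , t + 1L]
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      r <- r_nodes[iy]; c <- c_nodes[ix]
      if (!roi_ok(r, c)) next
      center <- (c - 1L) * d[1] + r
      s0 <- f0[center + patch_off]
      s0 <- s0 - mean(s0)
      s0_ss <- sum(s0^2)
      if (s0_ss <= .Machine$double.eps) next   # constant source: invalid
      # all candidate patches of f1 as an n_lags x npx matrix
      idx <- outer(center + lag_off, patch_off, "+")
      P <- matrix(f1[idx], nrow = n_off^2)
      pm <- rowMeans(P)
      num <- as.vector(P %*% s0)
      den <- sqrt(pmax(rowSums(P^2) - npx * pm^2, 0) * s0_ss)
      cc <- ifelse(den > .Machine$double.eps, num / den, -Inf)
      best <- max(cc)
      if (!is.finite(best)) next
      cand <- which(cc == best)
      if (length(cand) > 1L) {   # tie: smaller displacement wins
        cand <- cand[order(abs(lag_dx[cand]) + abs(lag_dy[cand]))][1L]
      }
      dy <- lag_dy[cand]; dx <- lag_dx[cand]
      # 3-point refinement (skipped at the lag-range boundary, and at an
      # exact match where the integer peak is already the answer)
      ccm <- matrix(cc, n_off, n_off)
      ry <- dy + m + 1L; rx <- dx + m + 1L
      exact <- best >= 1 - 1e-9
      sub_y <- if (!exact && ry > 1 && ry < n_off)
        subpixel_offset(ccm[ry - 1, rx], ccm[ry, rx], ccm[ry + 1, rx]) else 0
      sub_x <- if (!exact && rx > 1 && rx < n_off)
        subpixel_offset(ccm[ry, rx - 1], ccm[ry, rx], ccm[ry, rx + 1]) else 0
      corr[iy, ix, t] <- best
      u[iy, ix, t] <- (dx + sub_x) * ps
      v[iy, ix, t] <- (dy + sub_y) * ps
      valid[iy, ix, t] <- best >= params$corr_threshold
    }
  }
  u[!valid] <- NA_real_
  v[!valid] <- NA_real_

  structure(list(x_um = (c_nodes - 1) * ps, y_um = (r_nodes - 1) * ps,
                 u = u, v = v, corr = corr, valid = valid,
                 frame_interval_min = stack$frame_interval_min,
                 grid_size_um = grid_px * ps, params = params,
                 interpolated = FALSE),
            class = "piv_field_series")
}

#' @export
print.piv_field_series <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf(paste0("piv_field_series: %d x %d grid, %d frame pair(s), ",
                     "%.0f%% valid%s\n"),
              d[1], d[2], d[3], 100 * mean(x$valid),
              if (isTRUE(x$interpolated)) ", interpolated" else ""))
  invisible(x)
}

#' Build a displacement field series directly from arrays
#'
#' Constructor used by the statistics stages and by tests to assemble a
#' field series without running correlation (e.g. from ground-truth flow).
#'
#' @param x_um,y_um grid coordinates (um, regular spacing).
#' @param u,v displacement arrays `[ny, nx, nt]` in um/frame.
#' @param valid logical array; defaults to finite u.
#' @param frame_interval_min minutes per frame pair.
#' @param interpolated logical flag.
#' @return a `piv_field_series`.
#' @export
field_series <- function(x_um, y_um, u, v, valid = NULL,
                         frame_interval_min = 1, interpolated = FALSE) {
  if (length(dim(u)) == 2L) { u <- array(u, c(dim(u), 1L)); v <- array(v, c(dim(v), 1L)) }
  if (is.null(valid)) valid <- is.finite(u) & is.finite(v)
  if (length(dim(valid)) == 2L) valid <- array(valid, dim(u))
  stopifnot(dim(u)[1] == length(y_um), dim(u)[2] == length(x_um),
            all(dim(u) == dim(v)))
  gs <- if (length(x_um) > 1) diff(x_um)[1] else
        if (length(y_um) > 1) diff(y_um)[1] else 1
  structure(list(x_um = x_um, y_um = y_um, u = u, v = v,
                 corr = array(1, dim(u)), valid = valid,
                 frame_interval_min = frame_interval_min,
                 grid_size_um = gs, params = NULL,
                 interpolated = interpolated),
            class = "piv_field_series")
}
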