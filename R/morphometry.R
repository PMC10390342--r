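#' Elliptical-cylinder volume and surface area from tissue dimensions
#'
#' Idealises the tissue as a cylinder of length `L` with an elliptical
#' cross-section of width `W` and height `H`:
#' `volume = pi (W/2)(H/2) L`;
#' `surface_area = perimeter * L + 2 pi (W/2)(H/2)` with the ellipse
#' perimeter by Ramanujan's first approximation
#' `pi * (3(a+b) - sqrt((3a+b)(a+3b)))`. End caps are included (the
#' tissue surface is closed); relative changes are the quantities of
#' interest, not absolute areas.
#'
#' @param L,W,H length, width, height (um), all > 0. Vectors are accepted
#'   elementwise.
#' @return data.frame with `volume_um3` and `surface_area_um2`.
#' @export
cylinder_geometry <- function(L, W, H) {
  if (any(L <= 0) || any(W <= 0) || any(H <= 0))
    stop_config("tissue dimensions must be positive")
  a <- W / 2; b <- H / 2
  perim <- ellipse_perimeter(a, b)
  data.frame(volume_um3 = pi * a * b * L,
             surface_area_um2 = perim * L + 2 * pi * a * b)
}

#' Ramanujan's approximation to the ellipse perimeter
#'
#' `P = pi * (3(a+b) - sqrt((3a+b)(a+3b)))`; relative error below 1e-4 for
#' the moderate aspect ratios of nerve-cord cross-sections.
#'
#' @param a,b semi-axes.
#' @return perimeter.
#' @export
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Fit an ellipse to outline points and report eccentricity
#'
#' Direct algebraic least-squares conic fit constrained to an ellipse
#' (Fitzgibbon's method in the numerically stable Halir-Flusser form).
#' The outline is centred (centroid removed) before fitting; the fitted
#' ellipse's centre, semi-axes `a >= b`, orientation, eccentricity
#' `e = sqrt(a^2 - b^2) / a` (equal to the inter-focal distance over the
#' major axis length, `2c / 2a`), and RMS radial residual are returned.
#'
#' @param outline data.frame or matrix with x, y in the first two columns
#'   (>= 6 non-collinear points).
#' @return object of class `ellipse_fit`.
#' @export
fit_ellipse <- function(outline) {
  pts <- as.matrix(outline[, 1:2])
  if (nrow(pts) < 6) stop_config("need at least 6 outline points")
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
  scl <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(scl) || scl <= 0) stop_config("degenerate (collinear) outline")
  x <- x / scl; y <- y / scl

  # Halir & Flusser partitioned eigen-solve of the Fitzgibbon system
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  qrS3 <- qr(S3)
  if (qrS3$rank < 3) stop_config("degenerate (collinear) outline")
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop_config("no ellipse solution (degenerate input)")
  a1 <- evec[, ok[1]]
  coef <- c(a1, as.vector(Tm %*% a1))   # A B C D E F for centred, scaled data
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]

  # conic -> geometric parameters
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  theta <- 0.5 * atan2(B, A - C)
  Fo <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  lam <- eigen(matrix(c(A, B / 2, B / 2, C), 2))$values
  ax <- sqrt(-Fo / lam)                 # semi-axes (scaled units)
  a_s <- max(ax); b_s <- min(ax)
  if (ax[1] < ax[2]) theta <- theta + pi / 2
  theta <- atan2(sin(theta), cos(theta))

  a_um <- a_s * scl; b_um <- b_s * scl
  e <- sqrt(max(a_um^2 - b_um^2, 0)) / a_um

  # RMS radial residual in the ellipse frame
  xr <- (x * scl - cx * scl); yr <- (y * scl - cy * scl)
  xo <- xr * cos(theta) + yr * sin(theta)
  yo <- -xr * sin(theta) + yr * cos(theta)
  phi <- atan2(yo / b_um, xo / a_um)
  res <- sqrt(mean((xo - a_um * cos(phi))^2 + (yo - b_um * sin(phi))^2))

  structure(list(center = unname(c(cx * scl + ctr[1], cy * scl + ctr[2])),
                 a = a_um, b = b_um, orientation = theta,
                 eccentricity = e, residual_rms = res),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse_fit: a=%.3f b=%.3f e=%.4f theta=%.3f rad (rms %.3g)\n",
              x$a, x$b, x$eccentricity, x$orientation, x$residual_rms))
  invisible(x)
}

#' Centre an outline and align its major axis to the horizontal
#'
#' Convenience transform used before displaying cross-section outlines:
#' removes the fitted ellipse centre and rotates by minus the fitted
#' orientation.
#'
#' @param outline x, y point table.
#' @param fit optional precomputed [fit_ellipse()] result.
#' @return data.frame `x_um, y_um`.
#' @export
align_outline <- function(outline, fit = fit_ellipse(outline)) {
  pts <- as.matrix(outline[, 1:2])
  x <- pts[, 1] - fit$center[1]; y <- pts[, 2] - fit$center[2]
  th <- -fit$orientation
  data.frame(x_um = x * cos(th) - y * sin(th),
             y_um = x * sin(th) + y * cos(th))
}

# rasterise a simple polygon to a logical mask over grid (xs, ys) using the
# even-odd rule, vectorised over grid rows
polygon_mask <- function(poly_x, poly_y, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  n <- length(poly_x)
  mask <- matrix(FALSE, ny, nx)
  j <- n
  cross <- matrix(0L, ny, nx)
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    hit <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
    cross <- cross + hit
    j <- i
  }
  cross %% 2L == 1L
}

#' Interpolate sparse polygon annotations across z and integrate volume
#'
#' Reconstructs a volume from polygons drawn on sparse z-planes by
#' shape-based interpolation: each annotated polygon is rasterised, its
#' signed distance field computed, and intermediate slices are obtained by
#' linear interpolation of the signed distance between neighbouring
#' annotated planes (the zero level set morphs smoothly between shapes).
#' Volume is the sum of slice areas times the slice step, with slices
#' sampled at sub-step midpoints between annotated planes.
#'
#' @param polygons list of data.frames (`x_um, y_um`), one per annotated
#'   plane, in plane order (>= 2 planes; simple polygons).
#' @param z_positions_um z of each annotated plane (strictly monotone).
#' @param slice_step_um z sampling step for the reconstruction (um).
#' @param grid_step_um in-plane rasterisation step (um).
#' @return list with `volume_um3`, `slice_areas_um2`, `slice_z_um`.
#' @export
interpolate_annotations_z <- function(polygons, z_positions_um,
                                      slice_step_um = 1, grid_step_um = 0.25) {
  if (length(polygons) < 2) stop_config("need at least 2 annotated planes")
  stopifnot(length(polygons) == length(z_positions_um))
  ord <- order(z_positions_um)
  polygons <- polygons[ord]; z_positions_um <- z_positions_um[ord]
  if (any(diff(z_positions_um) <= 0))
    stop_config("z positions must be strictly monotone")
  for (p in polygons) {
    if (nrow(p) < 3) stop_config("polygons need >= 3 vertices")
    if (polygon_self_intersects(p[[1]], p[[2]]))
      stop_config("self-intersecting polygon annotation")
  }

  allx <- unlist(lapply(polygons, `[[`, 1))
  ally <- unlist(lapply(polygons, `[[`, 2))
  pad <- 2 * grid_step_um
  xs <- seq(min(allx) - pad, max(allx) + pad, by = grid_step_um)
  ys <- seq(min(ally) - pad, max(ally) + pad, by = grid_step_um)

  sdf <- lapply(polygons, function(p) {
    m <- polygon_mask(p[[1]], p[[2]], xs, ys)
    inside <- EBImage::distmap(m * 1)
    outside <- EBImage::distmap((1 - m) * 1)
    (inside - outside) * grid_step_um   # >0 inside
  })

  px_area <- grid_step_um^2
  areas <- c(); zs <- c()
  for (k in seq_len(length(polygons) - 1)) {
    z0 <- z_positions_um[k]; z1 <- z_positions_um[k + 1]
    nsub <- max(1L, round((z1 - z0) / slice_step_um))
    dz <- (z1 - z0) / nsub
    mid <- z0 + (seq_len(nsub) - 0.5) * dz
    for (zm in mid) {
      f <- (zm - z0) / (z1 - z0)
      s <- (1 - f) * sdf[[k]] + f * sdf[[k + 1]]
      areas <- c(areas, sum(s > 0) * px_area)
      zs <- c(zs, zm)
    }
  }
  steps <- rep(diff(z_positions_um) /
                 pmax(1, round(diff(z_positions_um) / slice_step_um)),
               times = pmax(1, round(diff(z_positions_um) / slice_step_um)))
  list(volume_um3 = sum(areas * steps), slice_areas_um2 = areas,
       slice_z_um = zs)
}

# segment-intersection test over non-adjacent polygon edges
polygon_self_intersects <- function(px, py) {
  n <- length(px)
  seg <- cbind(px, py, c(px[-1], px[1]), c(py[-1], py[1]))
  ccw <- function(ax, ay, bx, by, cx, cy)
    (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      a <- seg[i, ]; b <- seg[j, ]
      if (ccw(a[1], a[2], b[1], b[2], b[3], b[4]) !=
            ccw(a[3], a[4], b[1], b[2], b[3], b[4]) &&
          ccw(a[1], a[2], a[3], a[4], b[1], b[2]) !=
            ccw(a[1], a[2], a[3], a[4], b[3], b[4]))
        return(TRUE)
    }
  }
  FALSE
}
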