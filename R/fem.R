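# Minimal linear-elasticity FE core on trilinear hexahedra with B-bar
# (mean-dilatation) volumetric treatment, adequate for the near-
# incompressible core material. Internal unit system: um, nN, min ->
# stress in nN/um^2 (1 nN/um^2 = 1 kPa).

# hex local node coordinates (xi, eta, zeta), standard ordering
HEX_LOCAL <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                    ncol = 3, byrow = TRUE)

hex_shape_deriv <- function(xi) {
  # returns 8 x 3 matrix dN_a/dxi_l at point xi = c(xi, eta, zeta)
  t(vapply(seq_len(8), function(a) {
    s <- HEX_LOCAL[a, ]
    0.125 * c(s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]),
              s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]),
              s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]))
  }, numeric(3)))
}

hex_shape <- function(xi) {
  vapply(seq_len(8), function(a) {
    s <- HEX_LOCAL[a, ]
    0.125 * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3])
  }, numeric(1))
}

GP1 <- 1 / sqrt(3)
HEX_GP <- as.matrix(expand.grid(xi = c(-GP1, GP1), eta = c(-GP1, GP1),
                                zeta = c(-GP1, GP1)))

# Structured mesh of an axis-aligned capped cylinder of length L with an
# elliptical (or rectangular, for verification) cross-section W x H.
# x in [0, L]; cross-section mapped from the [-1,1]^2 reference square by
# the smooth square-to-disc map u*sqrt(1 - v^2/2), v*sqrt(1 - u^2/2).
fem_mesh_cylinder <- function(L, W, H, nx = 16, nc = 6,
                              section = c("ellipse", "rect")) {
  section <- match.arg(section)
  stopifnot(L > 0, W > 0, H > 0, nx >= 2, nc >= 2)
  us <- seq(-1, 1, length.out = nc + 1)
  xs <- seq(0, L, length.out = nx + 1)
  nid <- function(i, j, k) i * (nc + 1)^2 + k * (nc + 1) + j + 1L

  grid <- expand.grid(j = 0:nc, k = 0:nc, i = 0:nx)
  u <- us[grid$j + 1]; v <- us[grid$k + 1]
  if (section == "ellipse") {
    py <- u * sqrt(1 - v^2 / 2) * (W / 2)
    pz <- v * sqrt(1 - u^2 / 2) * (H / 2)
  } else {
    py <- u * (W / 2); pz <- v * (H / 2)
  }
  nodes <- cbind(x = xs[grid$i + 1], y = py, z = pz)

  el <- expand.grid(j = 0:(nc - 1), k = 0:(nc - 1), i = 0:(nx - 1))
  elems <- t(apply(el, 1, function(e) {
    i <- e[["i"]]; j <- e[["j"]]; k <- e[["k"]]
    c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k),
      nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1),
      nid(i, j + 1, k + 1))
  }))

  # boundary faces as 4-node quads + a label
  faces <- list()
  add_face <- function(n4, label) faces[[length(faces) + 1]] <<- c(n4, label)
  for (i in 0:(nx - 1)) for (k in 0:(nc - 1)) {
    add_face(c(nid(i, 0, k), nid(i + 1, 0, k),
               nid(i + 1, 0, k + 1), nid(i, 0, k + 1)), "lateral")
    add_face(c(nid(i, nc, k), nid(i + 1, nc, k),
               nid(i + 1, nc, k + 1), nid(i, nc, k + 1)), "lateral")
  }
  for (i in 0:(nx - 1)) for (j in 0:(nc - 1)) {
    add_face(c(nid(i, j, 0), nid(i + 1, j, 0),
               nid(i + 1, j + 1, 0), nid(i, j + 1, 0)), "lateral")
    add_face(c(nid(i, j, nc), nid(i + 1, j, nc),
               nid(i + 1, j + 1, nc), nid(i, j + 1, nc)), "lateral")
  }
  for (j in 0:(nc - 1)) for (k in 0:(nc - 1)) {
    add_face(c(nid(0, j, k), nid(0, j + 1, k),
               nid(0, j + 1, k + 1), nid(0, j, k + 1)), "head_cap")
    add_face(c(nid(nx, j, k), nid(nx, j + 1, k),
               nid(nx, j + 1, k + 1), nid(nx, j, k + 1)), "tail_cap")
  }
  face_nodes <- t(vapply(faces, function(f) as.integer(f[1:4]), integer(4)))
  face_label <- vapply(faces, function(f) f[5], character(1))

  list(nodes = nodes, elems = elems, face_nodes = face_nodes,
       face_label = face_label, L = L, W = W, H = H, nx = nx, nc = nc,
       section = section,
       head_nodes = which(nodes[, "x"] == 0),
       tail_nodes = which(nodes[, "x"] == L))
}

# cross-check that no element is inverted; returns min Jacobian determinant
fem_min_detJ <- function(mesh) {
  mn <- Inf
  dN_gp <- lapply(seq_len(nrow(HEX_GP)), function(g) hex_shape_deriv(HEX_GP[g, ]))
  for (e in seq_len(nrow(mesh$elems))) {
    X <- mesh$nodes[mesh$elems[e, ], ]
    for (g in seq_along(dN_gp)) {
      J <- t(dN_gp[[g]]) %*% X
      mn <- min(mn, det(J))
    }
  }
  mn
}

fem_material_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Global stiffness, B-bar mean-dilatation hexes. E in nN/um^2.
fem_stiffness <- function(mesh, E, nu) {
  D <- fem_material_matrix(E, nu)
  nel <- nrow(mesh$elems)
  ndof <- 3L * nrow(mesh$nodes)
  dN_gp <- lapply(seq_len(nrow(HEX_GP)), function(g) hex_shape_deriv(HEX_GP[g, ]))
  ngp <- length(dN_gp)
  m_vec <- c(1, 1, 1, 0, 0, 0)

  ii <- jj <- xx <- vector("list", nel)
  for (e in seq_len(nel)) {
    en <- mesh$elems[e, ]
    X <- mesh$nodes[en, ]
    dNdx_list <- vector("list", ngp)
    detJ <- numeric(ngp)
    for (g in seq_len(ngp)) {
      J <- t(dN_gp[[g]]) %*% X
      detJ[g] <- det(J)
      dNdx_list[[g]] <- dN_gp[[g]] %*% t(solve(J))
    }
    vol <- sum(detJ)
    # element-mean gradient row for the volumetric part (1 x 24)
    gbar <- numeric(24)
    for (g in seq_len(ngp)) {
      dNdx <- dNdx_list[[g]]
      grow <- numeric(24)
      grow[seq(1, 24, 3)] <- dNdx[, 1]
      grow[seq(2, 24, 3)] <- dNdx[, 2]
      grow[seq(3, 24, 3)] <- dNdx[, 3]
      gbar <- gbar + grow * detJ[g]
    }
    gbar <- gbar / vol

    ke <- matrix(0, 24, 24)
    for (g in seq_len(ngp)) {
      dNdx <- dNdx_list[[g]]
      B <- matrix(0, 6, 24)
      ix <- seq(1, 24, 3); iy <- ix + 1; iz <- ix + 2
      B[1, ix] <- dNdx[, 1]
      B[2, iy] <- dNdx[, 2]
      B[3, iz] <- dNdx[, 3]
      B[4, ix] <- dNdx[, 2]; B[4, iy] <- dNdx[, 1]
      B[5, iy] <- dNdx[, 3]; B[5, iz] <- dNdx[, 2]
      B[6, ix] <- dNdx[, 3]; B[6, iz] <- dNdx[, 1]
      grow <- numeric(24)
      grow[ix] <- dNdx[, 1]; grow[iy] <- dNdx[, 2]; grow[iz] <- dNdx[, 3]
      Bbar <- B + (1 / 3) * m_vec %o% (gbar - grow)
      ke <- ke + t(Bbar) %*% D %*% Bbar * detJ[g]
    }
    dofs <- as.vector(rbind(3 * en - 2, 3 * en - 1, 3 * en))
    ii[[e]] <- rep(dofs, times = 24)
    jj[[e]] <- rep(dofs, each = 24)
    xx[[e]] <- as.vector(ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# face geometry helper: outward-oriented normal, area-weighted, local frame
face_frame <- function(X4, body_centroid) {
  d1 <- X4[3, ] - X4[1, ]; d2 <- X4[4, ] - X4[2, ]
  n <- c(d1[2] * d2[3] - d1[3] * d2[2],
         d1[3] * d2[1] - d1[1] * d2[3],
         d1[1] * d2[2] - d1[2] * d2[1])
  n <- n / sqrt(sum(n^2))
  centroid <- colMeans(X4)
  if (sum(n * (centroid - body_centroid)) < 0) n <- -n
  list(n = n, centroid = centroid)
}

QUAD_LOCAL <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
QUAD_GP <- as.matrix(expand.grid(c(-GP1, GP1), c(-GP1, GP1)))

quad_shape <- function(xi)
  0.25 * (1 + QUAD_LOCAL[, 1] * xi[1]) * (1 + QUAD_LOCAL[, 2] * xi[2])

quad_shape_deriv <- function(xi)
  cbind(0.25 * QUAD_LOCAL[, 1] * (1 + QUAD_LOCAL[, 2] * xi[2]),
        0.25 * QUAD_LOCAL[, 2] * (1 + QUAD_LOCAL[, 1] * xi[1]))

# Equivalent nodal forces of a membrane prestress layer on boundary faces.
# sigma_fun(face_centroid, label) -> c(sigma_axial, sigma_circ) in nN/um.
# Returns the load vector to ADD to the RHS (already negated: K u = f).
fem_load_membrane <- function(mesh, sigma_fun) {
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  body_c <- colMeans(mesh$nodes)
  xhat <- c(1, 0, 0)
  for (fi in seq_len(nrow(mesh$face_nodes))) {
    fn <- mesh$face_nodes[fi, ]
    X4 <- mesh$nodes[fn, ]
    fr <- face_frame(X4, body_c)
    sg <- sigma_fun(fr$centroid, mesh$face_label[fi])
    if (all(sg == 0)) next
    # local frame: e1 along the axis projected on the face; caps (where the
    # projection degenerates) carry the circumferential tension isotropically
    e1 <- xhat - sum(xhat * fr$n) * fr$n
    n1 <- sqrt(sum(e1^2))
    if (n1 < 1e-8) {
      e1 <- c(0, 1, 0) - fr$n[2] * fr$n
      e1 <- e1 / sqrt(sum(e1^2))
      sg <- c(sg[2], sg[2])
    } else e1 <- e1 / n1
    e2 <- c(fr$n[2] * e1[3] - fr$n[3] * e1[2],
            fr$n[3] * e1[1] - fr$n[1] * e1[3],
            fr$n[1] * e1[2] - fr$n[2] * e1[1])
    P2 <- cbind((X4 - matrix(X4[1, ], 4, 3, byrow = TRUE)) %*% e1,
                (X4 - matrix(X4[1, ], 4, 3, byrow = TRUE)) %*% e2)
    floc <- numeric(8)
    for (g in seq_len(nrow(QUAD_GP))) {
      dN <- quad_shape_deriv(QUAD_GP[g, ])
      J2 <- t(dN) %*% P2
      detJ2 <- det(J2)
      dNdx <- dN %*% t(solve(J2))
      Bm <- matrix(0, 3, 8)
      i1 <- seq(1, 8, 2); i2 <- i1 + 1
      Bm[1, i1] <- dNdx[, 1]
      Bm[2, i2] <- dNdx[, 2]
      Bm[3, i1] <- dNdx[, 2]; Bm[3, i2] <- dNdx[, 1]
      floc <- floc + as.vector(t(Bm) %*% c(sg[1], sg[2], 0)) * abs(detJ2)
    }
    for (a in seq_len(4)) {
      gvec <- floc[2 * a - 1] * e1 + floc[2 * a] * e2
      dofs <- (3 * fn[a] - 2):(3 * fn[a])
      f[dofs] <- f[dofs] - gvec        # RHS: K u = -int B^T sigma dA
    }
  }
  f
}

# Uniform normal pressure P (nN/um^2, positive = compressive, applied on
# outward normals) on the faces selected by `labels`.
fem_load_pressure <- function(mesh, P, labels = c("lateral", "tail_cap")) {
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  body_c <- colMeans(mesh$nodes)
  for (fi in seq_len(nrow(mesh$face_nodes))) {
    if (!(mesh$face_label[fi] %in% labels)) next
    fn <- mesh$face_nodes[fi, ]
    X4 <- mesh$nodes[fn, ]
    fr <- face_frame(X4, body_c)
    for (g in seq_len(nrow(QUAD_GP))) {
      N <- quad_shape(QUAD_GP[g, ])
      dN <- quad_shape_deriv(QUAD_GP[g, ])
      Jg <- t(dN) %*% X4                 # 2 x 3 tangent map
      cr <- c(Jg[1, 2] * Jg[2, 3] - Jg[1, 3] * Jg[2, 2],
              Jg[1, 3] * Jg[2, 1] - Jg[1, 1] * Jg[2, 3],
              Jg[1, 1] * Jg[2, 2] - Jg[1, 2] * Jg[2, 1])
      dA <- sqrt(sum(cr^2))
      nrm <- cr / dA
      if (sum(nrm * fr$n) < 0) nrm <- -nrm
      dF <- -P * nrm * dA
      for (a in seq_len(4)) {
        dofs <- (3 * fn[a] - 2):(3 * fn[a])
        f[dofs] <- f[dofs] + N[a] * dF
      }
    }
  }
  f
}

# Solve K u = f with the given dofs fixed to zero. Returns full u.
fem_solve <- function(K, f, fixed_dofs) {
  ndof <- length(f)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- K[free, free, drop = FALSE]
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(Kff, f[free]))
  u
}

# mesh volume from (possibly displaced) nodal coordinates
fem_volume <- function(mesh, u = NULL) {
  nodes <- mesh$nodes
  if (!is.null(u)) nodes <- nodes + matrix(u, ncol = 3, byrow = TRUE)
  dN_gp <- lapply(seq_len(nrow(HEX_GP)), function(g) hex_shape_deriv(HEX_GP[g, ]))
  vol <- 0
  for (e in seq_len(nrow(mesh$elems))) {
    X <- nodes[mesh$elems[e, ], ]
    for (g in seq_along(dN_gp)) vol <- vol + det(t(dN_gp[[g]]) %*% X)
  }
  vol
}
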