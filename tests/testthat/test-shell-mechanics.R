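# One default model shared across blocks (stiffness assembly is the
# expensive part; loads and solves are cheap per case).
default_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_shell_model(
      stripe = list(center_um = 100, width_um = 20, scale = 0.2))
    m
  }
})

test_that("the mesh is valid, including at the wider reference geometry", {
  mesh <- vncmorph:::fem_mesh_cylinder(200, 40, 30, nx = 16, nc = 6)
  expect_gt(vncmorph:::fem_min_detJ(mesh), 0)
  expect_gt(vncmorph:::fem_min_detJ(default_model()$mesh), 0)
  expect_error(build_shell_model(nx = 15), "even")
  expect_error(build_shell_model(
    stripe = list(center_um = 100, width_um = 5, scale = 0.5)),
    "too coarse")
})

test_that("the core element passes uniaxial and hydrostatic patch tests", {
  mesh <- vncmorph:::fem_mesh_cylinder(10, 4, 2, nx = 4, nc = 2,
                                       section = "rect")
  K <- vncmorph:::fem_stiffness(mesh, 1, 0.3)
  hn <- mesh$head_nodes
  corner <- which(mesh$nodes[, 1] == 0 & mesh$nodes[, 2] == -2 &
                    mesh$nodes[, 3] == -1)
  upper <- which(mesh$nodes[, 1] == 0 & mesh$nodes[, 2] == -2 &
                   mesh$nodes[, 3] == 1)
  fix <- c(3 * hn - 2, 3 * corner - 1, 3 * corner, 3 * upper - 1)
  # end tension 0.5 (negative pressure on the tail cap)
  f <- vncmorph:::fem_load_pressure(mesh, -0.5, labels = "tail_cap")
  u <- matrix(vncmorph:::fem_solve(K, f, fix), ncol = 3, byrow = TRUE)
  expect_equal(unname(u[mesh$tail_nodes, 1]),
               rep(0.5 * 10, length(mesh$tail_nodes)), tolerance = 1e-9)
  # lateral contraction relative to the pinned y = -2 edge
  yext <- which(mesh$nodes[, 2] == 2)
  expect_equal(unname(u[yext, 2]), rep(-0.3 * 0.5 * 4, length(yext)),
               tolerance = 1e-9)
  # hydrostatic at near-incompressibility
  K49 <- vncmorph:::fem_stiffness(mesh, 0.1, 0.49)
  fall <- vncmorph:::fem_load_pressure(mesh, 0.01,
                                       labels = c("lateral", "tail_cap",
                                                  "head_cap"))
  u49 <- matrix(vncmorph:::fem_solve(K49, fall, fix), ncol = 3, byrow = TRUE)
  eps <- -0.01 / (3 * 0.1 / (3 * (1 - 2 * 0.49)))
  expect_equal(unname(u49[mesh$tail_nodes, 1]),
               rep(eps * 10, length(mesh$tail_nodes)), tolerance = 1e-6)
})

test_that("zero load gives zero displacement", {
  m <- default_model()
  r <- simulate_shell(m, "isotropic_tension", load_scale = 0)
  expect_equal(max(abs(r$u_um)), 0, tolerance = 1e-12)
})

test_that("load-case sign patterns hold across a 10x load sweep", {
  m <- default_model()
  for (s in c(1, 10)) {
    rp <- simulate_shell(m, "normal_pressure", load_scale = s,
                         use_stripe = FALSE)
    expect_lt(rp$dL_um, 0)
    expect_lt(rp$dW_um, 0)

    ri <- simulate_shell(m, "isotropic_tension", load_scale = s,
                         use_stripe = FALSE)
    expect_lt(ri$dL_um, 0)
    expect_lt(ri$dW_um, 0)
    expect_lt(ri$eccentricity_after, ri$eccentricity_before)   # rounding

    ra <- simulate_shell(m, "anisotropic_tension", load_scale = s,
                         use_stripe = FALSE)
    expect_lt(ra$dL_um, 0)
    expect_gt(ra$dW_um, 0)
    expect_gt(ra$dH_um, 0)
  }
})

test_that("tension load cases conserve core volume near incompressibility", {
  m <- default_model()
  for (lc in c("isotropic_tension", "anisotropic_tension")) {
    r <- simulate_shell(m, lc, use_stripe = FALSE)
    expect_lt(abs(r$volume_change_rel), 0.02)
  }
})

test_that("displacements are linear in the load", {
  m <- default_model()
  r1 <- simulate_shell(m, "anisotropic_tension", load_scale = 0.5,
                       use_stripe = FALSE)
  r2 <- simulate_shell(m, "anisotropic_tension", load_scale = 1,
                       use_stripe = FALSE)
  expect_equal(r1$u_um, r2$u_um / 2, tolerance = 1e-9)
})

test_that("mid-sagittal symmetry of loads yields mirror-symmetric fields", {
  m <- default_model()
  r <- simulate_shell(m, "anisotropic_tension", use_stripe = FALSE)
  nodes <- m$mesh$nodes
  # pair nodes mirrored in z: same x, y, opposite z
  key <- paste(round(nodes[, 1], 6), round(nodes[, 2], 6),
               round(abs(nodes[, 3]), 6))
  split_idx <- split(seq_len(nrow(nodes)), key)
  pairs <- Filter(function(i) length(i) == 2, split_idx)
  for (p in pairs[seq_len(min(50, length(pairs)))]) {
    i <- p[1]; j <- p[2]
    expect_equal(r$u_um[i, c("ux", "uy")], r$u_um[j, c("ux", "uy")],
                 tolerance = 1e-8)
    expect_equal(r$u_um[i, "uz"], -r$u_um[j, "uz"], tolerance = 1e-8)
  }
})

test_that("mesh refinement changes the length response by under 5%", {
  r1 <- simulate_shell(default_model(), "anisotropic_tension",
                       use_stripe = FALSE)
  m2 <- build_shell_model(nx = 32, nc = 12)
  r2 <- simulate_shell(m2, "anisotropic_tension")
  expect_lt(abs(r2$dL_um - r1$dL_um) / abs(r1$dL_um), 0.05)
})

test_that("a stripe tension reduction weakens tail motion monotonically", {
  m <- default_model()
  sp1 <- stripe_perturbation(m, scale = 1)
  expect_equal(sp1$perturbed$tail_displacement_um,
               sp1$base$tail_displacement_um, tolerance = 1e-9)
  tails <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    stripe_perturbation(m, scale = s)$perturbed$tail_displacement_um
  }, numeric(1))
  expect_lt(tails[1], tails[5])
  expect_true(all(diff(tails) >= -1e-9))
  sp02 <- stripe_perturbation(m, scale = 0.2)
  expect_lt(sp02$perturbed$tail_displacement_um,
            sp02$base$tail_displacement_um)
  # the stripe marks only the intended lateral faces
  sf <- vncmorph:::model_sigma_fun(m, 1e-4, 1e-5)
  expect_equal(sf(c(100, 20, 0), "lateral")[1], 0.1 * 0.2)
  expect_equal(sf(c(150, 20, 0), "lateral")[1], 0.1)
  expect_equal(sf(c(100, 0, 0), "tail_cap")[1], 0.1)
})
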