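test_that("single-element mass, stiffness and load match closed forms", {
  tri <- unit_triangle()
  M <- as.matrix(assemble_weighted_mass(tri))
  expect_equal(M,
               matrix(c(1/12, 1/24, 1/24,
                        1/24, 1/12, 1/24,
                        1/24, 1/24, 1/12), 3),
               ignore_attr = TRUE, tolerance = 1e-14)
  K <- as.matrix(assemble_weighted_stiffness(tri))
  expect_equal(K, 0.5 * matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3),
               ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(as.matrix(assemble_laplace(tri)), K, ignore_attr = TRUE)
  expect_equal(assemble_charge_load(tri, 1), rep(1/6, 3))
  expect_equal(assemble_charge_load(tri, 0), rep(0, 3))
})

test_that("constant potential factors out of the weighted mass matrix", {
  tri <- unit_triangle()
  M0 <- assemble_weighted_mass(tri)
  Mc <- assemble_weighted_mass(tri, phi = rep(2, 3), ratio = 1.5)
  expect_equal(as.matrix(Mc), exp(-3) * as.matrix(M0), tolerance = 1e-12)
})

test_that("weighted matrices match a high-order quadrature oracle", {
  tri <- unit_triangle()
  phi <- c(0, 0.01, 0.02)   # linear potential at the per-element scale of
                            # the reference runs (h * |grad phi|)
  Mw <- as.matrix(assemble_weighted_mass(tri, phi, ratio = 1, degree = 4))
  lam <- list(function(x, y) 1 - x - y, function(x, y) x, function(x, y) y)
  for (l in 1:3) for (s in l:3) {
    exact <- tri_integral_oracle(function(x, y) {
      exp(-(phi[1] * lam[[1]](x, y) + phi[2] * lam[[2]](x, y) +
              phi[3] * lam[[3]](x, y))) * lam[[l]](x, y) * lam[[s]](x, y)
    })
    expect_equal(Mw[l, s], exact, tolerance = 1e-8)
  }
  # stiffness: constant gradients, weight enters via its element average
  Kw <- as.matrix(assemble_weighted_stiffness(tri, phi, d = 2, ratio = 1,
                                              degree = 4))
  grads <- list(c(-1, -1), c(1, 0), c(0, 1))
  wbar <- tri_integral_oracle(function(x, y) {
    exp(-(phi[1] * lam[[1]](x, y) + phi[2] * lam[[2]](x, y) +
            phi[3] * lam[[3]](x, y)))
  })
  for (l in 1:3) for (s in 1:3) {
    expect_equal(Kw[l, s], 2 * wbar * sum(grads[[l]] * grads[[s]]),
                 tolerance = 1e-8)
  }
})

test_that("assembled operators keep their structural identities", {
  mesh <- mesh_ellipse(2, 1, 0.3)
  phi <- sin(mesh$nodes[, 1]) * 0.5
  Mw <- assemble_weighted_mass(mesh, phi, ratio = 1)
  Kw <- assemble_weighted_stiffness(mesh, phi, d = 1, ratio = 1)
  expect_lt(max(abs(Mw - Matrix::t(Mw))), 1e-12 * max(abs(Mw)))
  expect_lt(max(abs(Kw - Matrix::t(Kw))), 1e-12 * max(abs(Kw)))
  expect_gte(min(Mw@x), 0)
  # row sums of the weighted stiffness vanish (gradients sum to zero)
  rs <- as.vector(Kw %*% rep(1, nrow(mesh$nodes)))
  expect_lt(max(abs(rs)), 1e-12 * max(abs(Kw)))
  # linearity in d
  K2 <- assemble_weighted_stiffness(mesh, phi, d = 2, ratio = 1)
  expect_equal(as.matrix(K2), 2 * as.matrix(Kw), tolerance = 1e-14)
  # unweighted mass spreads nodal area shares summing to the domain area
  M0 <- assemble_weighted_mass(mesh)
  expect_equal(sum(M0 %*% rep(1, nrow(mesh$nodes))), mesh_area(mesh),
               tolerance = 1e-12)
  # charge load sums to f * area
  beta <- assemble_charge_load(mesh, 0.1)
  expect_equal(sum(beta), 0.1 * mesh_area(mesh), tolerance = 1e-12)
})

test_that("laplace matrix is PSD with constants in its kernel, PD inside", {
  mesh <- mesh_ellipse(1, 1, 0.35)
  Q <- assemble_laplace(mesh)
  expect_lt(max(abs(Q %*% rep(1, nrow(mesh$nodes)))), 1e-13)
  ev <- eigen(as.matrix(Q[mesh$interior, mesh$interior]),
              symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("quadrature-degree refinement barely moves smooth-weight entries", {
  # exponent at the scale the potential actually reaches during the
  # reference time stepping (weak coupling, sub-mV potentials)
  mesh <- mesh_ellipse(2, 1, 0.3)
  kin <- kinetics_basic()
  cfg <- solver_config(dt = 1e-3, T = 1e-3)
  st <- initialize_state(mesh, kin$species, cfg)
  st <- advance(st, mesh, kin, cfg)
  M2 <- assemble_weighted_mass(mesh, st$zeta, ratio = 1, degree = 2)
  M4 <- assemble_weighted_mass(mesh, st$zeta, ratio = 1, degree = 4)
  expect_lt(max(abs(M2 - M4)) / max(abs(M4)), 1e-3)
  # even for O(1) exponents the rules stay within a percent of each other
  phi <- 0.5 * mesh$nodes[, 1]
  M2b <- assemble_weighted_mass(mesh, phi, ratio = 1, degree = 2)
  M4b <- assemble_weighted_mass(mesh, phi, ratio = 1, degree = 4)
  expect_lt(max(abs(M2b - M4b)) / max(abs(M4b)), 1e-2)
})

test_that("reaction load reduces to the charge load for constant rates", {
  tri <- unit_triangle()
  Z <- matrix(1, 3, 1)
  lv <- assemble_reaction_load(tri, function(C) matrix(3, nrow(C), 1),
                               phi = NULL, Z = Z, ratios = 0,
                               species_index = 1)
  expect_equal(lv, rep(3 / 6, 3))
  zero <- assemble_reaction_load(tri, function(C) matrix(0, nrow(C), 1),
                                 phi = NULL, Z = Z, ratios = 0,
                                 species_index = 1)
  expect_equal(zero, rep(0, 3))
  expect_error(
    assemble_reaction_load(tri, function(C) matrix(NaN, nrow(C), 1),
                           phi = NULL, Z = Z, ratios = 0, species_index = 1),
    "non-finite"
  )
})

test_that("Michaelis-Menten reaction load matches the quadrature oracle", {
  tri <- unit_triangle()
  p <- list(k2 = 2, kM = 5, C10 = 1)
  Z <- matrix(c(0.2, 0.6, 1.0), 3, 1)     # linear substrate field
  lv <- assemble_reaction_load(
    tri, function(C) matrix(mm_reduced_rate(C[, 1], p), ncol = 1),
    phi = NULL, Z = Z, ratios = 0, species_index = 1, degree = 4
  )
  lam <- list(function(x, y) 1 - x - y, function(x, y) x, function(x, y) y)
  for (s in 1:3) {
    exact <- tri_integral_oracle(function(x, y) {
      c2 <- Z[1] * lam[[1]](x, y) + Z[2] * lam[[2]](x, y) +
        Z[3] * lam[[3]](x, y)
      p$k2 * p$C10 * c2 / (c2 + p$kM) * lam[[s]](x, y)
    })
    expect_equal(lv[s], exact, tolerance = 1e-6)
  }
})

test_that("L2 norm agrees with closed forms", {
  mesh <- mesh_ellipse(2, 1, 0.2)
  one <- rep(1, nrow(mesh$nodes))
  expect_equal(l2_norm(mesh, one), sqrt(mesh_area(mesh)), tolerance = 1e-12)
  expect_identical(l2_norm(mesh, 0 * one), 0)
  disk <- mesh_ellipse(1, 1, 0.1)
  vx <- disk$nodes[, 1]
  expect_equal(l2_norm(disk, vx), sqrt(pi / 4), tolerance = 5e-3)
})

test_that("matrices export to MatrixMarket", {
  tri <- unit_triangle()
  path <- tempfile(fileext = ".mtx")
  write_mtx(assemble_laplace(tri), path)
  expect_true(file.exists(path))
  expect_match(readLines(path, n = 1), "MatrixMarket")
})
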