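test_that("state initialisation applies the Slotboom weight to C0", {
  mesh <- mesh_ellipse(1, 1, 0.3)
  cfg <- solver_config(dt = 1e-3, T = 1e-2)
  sp <- rbind(species_spec("A", 1e-3, 1, 2), species_spec("B", 1e-3, 1, 0))

  # phi0 = 0: Z0 equals the nodal initial concentration
  st0 <- initialize_state(mesh, sp, cfg, phi0 = 0)
  expect_equal(st0$xi[, 1], rep(2, nrow(mesh$nodes)))
  expect_equal(st0$xi[, 2], rep(0, nrow(mesh$nodes)))

  # phi0 = -80 mV, m/d = 1: interior p0 = exp(-80/25.693)
  st <- initialize_state(mesh, sp, cfg, phi0 = -80)
  p0 <- exp(-80 / 25.693)
  expect_equal(st$xi[mesh$interior, 1],
               rep(2 * p0, length(mesh$interior)), tolerance = 1e-12)
  expect_equal(st$xi[mesh$boundary, 1], rep(2, length(mesh$boundary)))
  expect_true(all(st$zeta[mesh$boundary] == 0))

  sp_bad <- sp; sp_bad$C0[1] <- -1
  expect_error(initialize_state(mesh, sp_bad, cfg), "nonnegative")
})

test_that("uniform fields with no reaction, charge or fixed charge are steady", {
  mesh <- mesh_ellipse(2, 1, 0.3)
  sp <- rbind(species_spec("A", 1e-3, 0, 5), species_spec("B", 2e-3, 0, 1))
  kin <- kinetics_custom(sp, list(list(), list()), name = "inert")
  cfg <- solver_config(dt = 1e-2, T = 5e-2)
  tr <- simulate(mesh, kin, cfg, epsilon = 1, f = 0, phi0 = 0)
  expect_lt(max(abs(tr$final$C[, 1] - 5)), 1e-10)
  expect_lt(max(abs(tr$final$C[, 2] - 1)), 1e-10)
  expect_equal(convergence_error(tr, cfg$dt), 0)
})

test_that("discrete total mass is conserved for reaction-free charged species", {
  # charged species + fixed charge give a nontrivial potential, so the
  # Slotboom weights genuinely vary; conservation is an identity of the
  # scheme (weighted-stiffness rows sum to zero)
  mesh <- mesh_ellipse(2, 1, 0.3)
  sp <- rbind(species_spec("A", 1e-3, 1, 2), species_spec("B", 2e-3, -1, 1))
  kin <- kinetics_custom(sp, list(list(), list()), name = "inert")
  cfg <- solver_config(dt = 1e-2, T = 1)
  ctx <- pnpfem:::step_context(mesh, sp, cfg)
  state <- initialize_state(mesh, sp, cfg, phi0 = -80)
  mass <- function(st) {
    vapply(1:2, function(i) {
      A <- assemble_weighted_mass(mesh, st$zeta, sp$m[i] / sp$d[i])
      sum(A %*% st$xi[, i])
    }, numeric(1))
  }
  m0 <- mass(state)
  for (n in 1:10) {
    state <- advance(state, mesh, kin, cfg, epsilon = 1, f = 0.1,
                     species = sp, ctx = ctx)
    expect_lt(max(abs(mass(state) - m0) / m0), 1e-10)
  }
  # the potential is genuinely nonzero in this run
  expect_gt(max(abs(state$zeta)), 1e-3)
})

test_that("well-mixed limit matches the scalar Picard oracle (basic)", {
  mesh <- mesh_ellipse(1, 1, 0.3)
  area <- mesh_area(mesh)
  kin <- kinetics_basic(k2 = 5, kM = 2, C10 = 1,
                        species = neutralize(basic_species(C10 = 1, C20 = 3)))
  cfg <- solver_config(dt = 0.05, T = 0.25, eps = 1e-9)
  tr <- simulate(mesh, kin, cfg, epsilon = 1, f = 0, phi0 = 0)
  c <- c(1, 3, 0)
  for (n in 1:5) {
    c <- scalar_basic_step(c, cfg$dt, kin$params, cfg$eps, sqrt(area))
    row <- tr$probes[n + 1, c("E", "S", "P")]
    expect_equal(as.numeric(row), c, tolerance = 1e-8)
    # the fields stay spatially uniform
  }
  expect_lt(diff(range(tr$final$C[, 2])) / mean(tr$final$C[, 2]), 1e-10)
})

test_that("well-mixed limit matches the scalar Picard oracle (sweep models)", {
  mesh <- mesh_ellipse(1, 1, 0.3)
  area <- mesh_area(mesh)

  kin_s <- kinetics_suicide(species = neutralize(suicide_species()))
  cfg <- solver_config(dt = 0.02, T = 0.1, eps = 1e-9)
  tr <- simulate(mesh, kin_s, cfg, epsilon = 1, f = 0, phi0 = 0)
  c <- c(0.5, 0.5, 0, 0, 0, 0)
  for (n in 1:5) {
    c <- scalar_suicide_step(c, cfg$dt, kin_s$params, cfg$eps, sqrt(area))
    expect_equal(as.numeric(tr$probes[n + 1, 2:7]), c, tolerance = 1e-8)
  }

  kin_c <- kinetics_cooperative(species = neutralize(cooperative_species()))
  tr2 <- simulate(mesh, kin_c, cfg, epsilon = 1, f = 0, phi0 = 0)
  c2 <- c(0.5, 0.5, 0, 0, 0)
  for (n in 1:5) {
    c2 <- scalar_cooperative_step(c2, cfg$dt, kin_c$params, cfg$eps,
                                  sqrt(area))
    expect_equal(as.numeric(tr2$probes[n + 1, 2:6]), c2, tolerance = 1e-8)
  }
})

test_that("simulation bookkeeping: step count, determinism, diagnostics", {
  mesh <- mesh_ellipse(2, 1, 0.4)
  kin <- kinetics_basic()
  cfg <- solver_config(dt = 1e-3, T = 0.0105)   # non-multiple: ceil -> 11
  tr <- simulate(mesh, kin, cfg)
  expect_identical(nrow(tr$diagnostics$max_inc), 11L)
  expect_identical(nrow(tr$probes), 12L)
  tr2 <- simulate(mesh, kin, cfg)
  expect_identical(tr$probes, tr2$probes)
  expect_true(all(tr$diagnostics$converged))
  expect_true(all(tr$diagnostics$max_inc >= 0))
  expect_identical(sum(tr$diagnostics$negative_nodes), 0L)
})

test_that("basic reference dynamics: substrate falls, product mirrors it", {
  mesh <- mesh_ellipse(2, 1, 0.3)
  cfg <- solver_config(dt = 1e-3, T = 0.05)
  tr <- simulate(mesh, kinetics_basic(), cfg)
  s <- tr$probes$S
  p <- tr$probes$P
  expect_true(all(diff(s) <= 1e-9))
  expect_true(all(diff(p) >= -1e-9))
  # mirror image: S + P stays at the initial substrate level
  expect_lt(max(abs(s + p - 800)) / 800, 0.01)
  # free enzyme stays flat
  expect_lt(max(abs(tr$probes$E - 1)), 0.02)
})

test_that("Picard non-convergence is flagged per the configured policy", {
  mesh <- mesh_ellipse(1, 1, 0.4)
  kin <- kinetics_basic()
  cfg <- solver_config(dt = 1e-3, T = 2e-3, eps = 1e-16, max_picard = 2L)
  expect_warning(simulate(mesh, kin, cfg), "did not reach")
  cfg2 <- solver_config(dt = 1e-3, T = 2e-3, eps = 1e-16, max_picard = 2L,
                        on_nonconvergence = "abort")
  expect_error(suppressWarnings(simulate(mesh, kin, cfg2)), "did not reach")
})

test_that("probe CSV and VTK snapshots are written", {
  mesh <- mesh_ellipse(1, 1, 0.4)
  kin <- kinetics_basic()
  cfg <- solver_config(dt = 1e-3, T = 4e-3, snapshot_every = 2L)
  dir <- tempfile()
  tr <- simulate(mesh, kin, cfg, snapshot_dir = dir)
  expect_true(file.exists(file.path(dir, "snapshot_000000.vtk")))
  expect_true(file.exists(file.path(dir, "snapshot_000004.vtk")))
  expect_true(file.exists(file.path(dir, "series_index.csv")))
  head1 <- readLines(file.path(dir, "snapshot_000004.vtk"), n = 1)
  expect_match(head1, "vtk DataFile")
  csv <- tempfile(fileext = ".csv")
  write_probes_csv(tr, csv)
  got <- utils::read.csv(csv)
  expect_equal(got$S, tr$probes$S, tolerance = 1e-15)
})

test_that("suicide substrate exhausts monotonically, matching the ODE oracle", {
  skip_if_not_installed("deSolve")
  # (1+r)*mu = 6 > 1: the substrate must be driven to zero, but the printed
  # rate constants set the 1%-of-s0 crossing near t = 9.4 s, not t = 4 s
  mesh <- mesh_ellipse(2, 1, 0.25)
  kin <- kinetics_suicide()
  cfg <- solver_config(dt = 2e-2, T = 10, eps = 1e-4)
  tr <- simulate(mesh, kin, cfg)
  S <- tr$probes$S
  expect_true(all(diff(S) <= 1e-9))
  expect_lt(S[length(S)] / 0.5, 0.01)
  # centre probe at t = 4 agrees with the well-mixed stiff ODE solution
  ode <- deSolve::ode(c(0.5, 0.5, 0, 0, 0, 0), c(0, 4),
                      function(t, y, parms) list(suicide_rates(y, kin$params)),
                      NULL, method = "lsoda")
  s4_ode <- ode[2, 3]
  s4_fem <- tr$probes$S[which.min(abs(tr$probes$time - 4))]
  expect_lt(abs(s4_fem - s4_ode) / s4_ode, 0.05)
})
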