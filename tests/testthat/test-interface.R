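basic_cfg_path <- function() {
  system.file("extdata", "basic.yaml", package = "pnpfem")
}

test_that("bundled reference configurations load with converted units", {
  cfg <- load_config(basic_cfg_path())
  kin <- cfg$kinetics
  expect_identical(kin$name, "basic")
  expect_identical(nrow(kin$species), 3L)
  expect_equal(kin$species$z, c(1, 0, 1))
  expect_equal(cfg$solver$dt, 1e-3)
  expect_equal(cfg$solver$T, 0.2)
  expect_equal(kin$params$kM, 90)       # 9e-5 M -> 90 muM
  expect_equal(kin$params$k2, 1.4e4)
  expect_equal(kin$species$C0, c(1, 800, 0))
  expect_equal(cfg$phi0, -80)
  expect_equal(cfg$f, 0.1)

  cfg_s <- load_config(system.file("extdata", "suicide.yaml",
                                   package = "pnpfem"))
  expect_equal(cfg_s$kinetics$params$k3, 10)
  expect_equal(cfg_s$kinetics$species$d,
               c(1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6))
  expect_equal(cfg_s$solver$dt, 1e-2)

  cfg_c <- load_config(system.file("extdata", "cooperative.yaml",
                                   package = "pnpfem"))
  expect_equal(cfg_c$kinetics$params$K1, 1000)
  expect_equal(cfg_c$kinetics$params$k1, 0.002)
  expect_equal(cfg_c$kinetics$params$k3, 2000)
})

test_that("schema violations are collected and reported together", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "domain: {a: 2, b: 1, h: 0.3}",
    "model: {preset: basic}",
    "solver: {T: 0.1, nonsense: 1}",
    "mystery: true"
  ), bad)
  err <- tryCatch(load_config(bad), error = function(e) conditionMessage(e))
  expect_match(err, "solver.dt")
  expect_match(err, "nonsense")
  expect_match(err, "mystery")

  unk <- tempfile(fileext = ".yaml")
  writeLines(c(
    "domain: {a: 2, b: 1, h: 0.3}",
    "model: {preset: basic, constants: {kM: {value: 1, unit: parsec}}}",
    "solver: {dt: 0.001, T: 0.1}"
  ), unk)
  expect_error(load_config(unk), "unknown unit")
  expect_error(load_config(tempfile()), "not found")
})

test_that("configurations round-trip through save and reload", {
  cfg <- load_config(basic_cfg_path())
  out <- tempfile(fileext = ".yaml")
  save_config(cfg, out)
  cfg2 <- load_config(out)
  expect_identical(cfg$raw, cfg2$raw)
  expect_equal(cfg$kinetics$species, cfg2$kinetics$species)
})

test_that("config_mesh builds from geometry or reads a mesh file", {
  cfg <- load_config(basic_cfg_path())
  cfg$domain$h <- 0.4
  mesh <- config_mesh(cfg)
  expect_s3_class(mesh, "pnp_mesh")
  msh <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, msh)
  cfg$domain <- list(mesh = msh)
  mesh2 <- config_mesh(cfg)
  expect_equal(mesh2$nodes, mesh$nodes, ignore_attr = TRUE)
})

write_fast_config <- function(path, extra = character(0)) {
  writeLines(c(
    "domain: {a: 2.0, b: 1.0, h: 0.45}",
    "model:",
    "  preset: basic",
    "  constants: {k2: 1.4e4, kM: {value: 9.0e-5, unit: M}, C10: 1.0}",
    "epsilon: 1.0e6",
    "fixed_charge: 0.1",
    "phi0: {value: -80, unit: mV}",
    "solver: {dt: 1.0e-3, T: 5.0e-3, eps: 1.0e-4}",
    extra
  ), path)
  path
}

test_that("command line: simulate writes probes, manifest; outputs reproducible", {
  cfgp <- write_fast_config(tempfile(fileext = ".yaml"))
  out1 <- tempfile(); out2 <- tempfile()
  expect_identical(run_cli(c("simulate", "--config", cfgp, "--out", out1,
                             "--seed", "7")), 0L)
  expect_true(file.exists(file.path(out1, "probes.csv")))
  expect_true(file.exists(file.path(out1, "manifest.yaml")))
  man <- yaml::read_yaml(file.path(out1, "manifest.yaml"))
  expect_identical(man$seed, 7L)
  expect_gt(man$mesh$triangles, 0)
  expect_identical(run_cli(c("simulate", "--config", cfgp, "--out", out2)),
                   0L)
  expect_identical(readLines(file.path(out1, "probes.csv")),
                   readLines(file.path(out2, "probes.csv")))
})

test_that("command line: mesh/stability subcommands and error paths", {
  cfgp <- write_fast_config(tempfile(fileext = ".yaml"))
  out <- tempfile()
  expect_identical(run_cli(c("mesh", "--config", cfgp, "--out", out)), 0L)
  expect_true(file.exists(file.path(out, "mesh.msh")))
  expect_true(file.exists(file.path(out, "mesh.node")))

  expect_identical(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(run_cli(character(0))), 2L)
  expect_identical(suppressMessages(
    run_cli(c("simulate", "--config", tempfile()))
  ), 1L)

  st <- tempfile()
  expect_identical(suppressMessages(
    run_cli(c("stability", "--config", cfgp, "--out", st,
              "--dt", "1e-3,5e-4", "--T", "5e-3"))
  ), 0L)
  tab <- utils::read.csv(file.path(st, "stability.csv"))
  expect_identical(nrow(tab), 1L)
  expect_lt(tab$rel_discrepancy, 0.02)
})

test_that("command line: convergence subcommand writes a decreasing table", {
  cfgp <- write_fast_config(tempfile(fileext = ".yaml"))
  out <- tempfile()
  expect_identical(suppressMessages(
    run_cli(c("convergence", "--config", cfgp, "--out", out,
              "--h", "0.45,0.3", "--T", "0.02"))
  ), 0L)
  tab <- utils::read.csv(file.path(out, "convergence.csv"))
  expect_identical(nrow(tab), 2L)
  expect_true(all(diff(tab$E_h) < 0))
  expect_equal(tab$dt, c(0.45, 0.3) * 0.02 / 16)
})
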