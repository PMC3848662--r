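# Run configuration: YAML schema, validation, unit conversion.
#
# Internal units are muM (concentration), s (time), mV (potential entering
# the thermal-voltage scaling), simulation length units (geometry). Any
# numeric entry may be written as `{value: x, unit: u}`; molar
# concentrations and M^-1 s^-1 binding constants are converted on load.

config_unit_factors <- list(
  "uM" = 1, "µM" = 1, "M" = 1e6, "mM" = 1e3,
  "mV" = 1, "s" = 1, "ms" = 1e-3,
  "M-1s-1" = 1e-6, "uM-1s-1" = 1
)

convert_value <- function(x, where, violations) {
  if (is.list(x)) {
    if (is.null(x$value) || is.null(x$unit)) {
      violations$add(sprintf("%s: value/unit entry needs both fields", where))
      return(NA_real_)
    }
    fac <- config_unit_factors[[as.character(x$unit)]]
    if (is.null(fac)) {
      violations$add(sprintf("%s: unknown unit '%s'", where, x$unit))
      return(NA_real_)
    }
    return(as.numeric(x$value) * fac)
  }
  as.numeric(x)
}

violation_collector <- function() {
  msgs <- character(0)
  list(
    add = function(m) msgs <<- c(msgs, m),
    get = function() msgs
  )
}

check_keys <- function(x, allowed, where, violations) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    violations$add(sprintf("%s: unknown key(s) %s", where,
                           paste(sQuote(unknown), collapse = ", ")))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates its schema (every violation is
#' listed in one error), applies unit conversions (molar concentrations to
#' muM, `M-1s-1` binding constants to `muM^-1 s^-1`) and instantiates the
#' kinetics preset and solver configuration. Three bundled reference
#' configurations reproduce the basic, suicide-substrate and cooperative
#' runs: `system.file("extdata", "basic.yaml", package = "pnpfem")` etc.
#'
#' @param path YAML file path.
#' @return a `pnp_config`: list with `domain`, `kinetics`, `epsilon`, `f`,
#'   `phi0` (mV), `solver` (a [solver_config()]), `probes`, `output`, and
#'   the raw parsed list in `$raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  vio <- violation_collector()
  check_keys(raw, c("domain", "model", "species", "epsilon", "fixed_charge",
                    "phi0", "solver", "probes", "output"), "top level", vio)

  # --- solver ---
  if (is.null(raw$solver)) {
    vio$add("solver: section missing")
    solver <- NULL
  } else {
    check_keys(raw$solver, c("dt", "T", "eps", "max_picard",
                             "quadrature_degree", "V_T", "clamp",
                             "on_nonconvergence", "snapshot_every"),
               "solver", vio)
    for (req in c("dt", "T")) {
      if (is.null(raw$solver[[req]])) {
        vio$add(sprintf("solver.%s: required field missing", req))
      }
    }
  }

  # --- domain ---
  if (is.null(raw$domain)) {
    vio$add("domain: section missing")
  } else {
    check_keys(raw$domain, c("a", "b", "h", "mesh"), "domain", vio)
    if (is.null(raw$domain$mesh) &&
        (is.null(raw$domain$a) || is.null(raw$domain$b) ||
         is.null(raw$domain$h))) {
      vio$add("domain: needs either a/b/h or a mesh file path")
    }
  }

  # --- model ---
  preset <- NULL
  if (is.null(raw$model) || is.null(raw$model$preset)) {
    vio$add("model.preset: required field missing")
  } else {
    check_keys(raw$model, c("preset", "constants", "terms"), "model", vio)
    preset <- raw$model$preset
    if (!preset %in% c("basic", "suicide", "cooperative", "custom")) {
      vio$add(sprintf("model.preset: unknown preset '%s'", preset))
    }
  }

  consts <- list()
  if (!is.null(raw$model$constants)) {
    allowed <- switch(preset,
      basic = c("k2", "kM", "C10"),
      suicide = c("k1", "km1", "k2", "k3", "k4", "e0", "s0"),
      cooperative = c("K1", "K2", "km1", "k2", "km3", "k4", "e0", "s0"),
      character(0)
    )
    check_keys(raw$model$constants, allowed, "model.constants", vio)
    for (nm in intersect(names(raw$model$constants), allowed)) {
      consts[[nm]] <- convert_value(raw$model$constants[[nm]],
                                    paste0("model.constants.", nm), vio)
    }
  }

  # convert unit-carrying scalars before flushing violations so that a bad
  # unit surfaces as a schema error, not a downstream failure
  dt <- if (!is.null(raw$solver$dt)) {
    convert_value(raw$solver$dt, "solver.dt", vio)
  }
  Tend <- if (!is.null(raw$solver$T)) {
    convert_value(raw$solver$T, "solver.T", vio)
  }
  phi0 <- if (is.null(raw$phi0)) -80 else convert_value(raw$phi0, "phi0", vio)

  msgs <- vio$get()
  if (length(msgs) > 0L) {
    stop("invalid configuration:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }

  kin <- if (preset == "custom") {
    sp <- config_species_table(raw$species, vio)
    terms <- lapply(raw$model$terms, function(sp_terms) {
      lapply(sp_terms, function(tm) {
        list(coef = as.numeric(tm$coef), powers = as.integer(tm$powers))
      })
    })
    kinetics_custom(sp, terms)
  } else {
    do.call(kinetics_preset, c(list(name = preset), consts))
  }
  if (preset != "custom" && !is.null(raw$species)) {
    kin$species <- apply_species_overrides(kin$species, raw$species, vio)
  }
  msgs <- vio$get()
  if (length(msgs) > 0L) {
    stop("invalid configuration:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }

  sv <- raw$solver
  solver <- solver_config(
    dt = dt,
    T = Tend,
    eps = if (is.null(sv$eps)) 1e-4 else as.numeric(sv$eps),
    max_picard = if (is.null(sv$max_picard)) 50L else as.integer(sv$max_picard),
    degree = if (is.null(sv$quadrature_degree)) 2 else sv$quadrature_degree,
    V_T = if (is.null(sv$V_T)) 25.693 else as.numeric(sv$V_T),
    clamp = if (is.null(sv$clamp)) 50 else as.numeric(sv$clamp),
    on_nonconvergence = if (is.null(sv$on_nonconvergence)) "warn"
                        else sv$on_nonconvergence,
    snapshot_every = if (is.null(sv$snapshot_every)) 0L
                     else as.integer(sv$snapshot_every)
  )

  probes <- if (is.null(raw$probes)) {
    rbind(c(0, 0))
  } else {
    do.call(rbind, lapply(raw$probes, as.numeric))
  }

  structure(
    list(
      domain = raw$domain,
      kinetics = kin,
      epsilon = if (is.null(raw$epsilon)) 1e6 else as.numeric(raw$epsilon),
      f = if (is.null(raw$fixed_charge)) 0.1 else as.numeric(raw$fixed_charge),
      phi0 = phi0,
      solver = solver,
      probes = probes,
      output = if (is.null(raw$output)) list(directory = "pnpfem_out")
               else raw$output,
      raw = raw,
      path = path
    ),
    class = "pnp_config"
  )
}

config_species_table <- function(sp_list, vio) {
  if (is.null(sp_list)) {
    vio$add("species: required for the custom preset")
    return(NULL)
  }
  do.call(rbind, lapply(sp_list, function(s) {
    species_spec(
      name = s$name,
      d = convert_value(s$d, paste0("species.", s$name, ".d"), vio),
      z = as.integer(s$z),
      C0 = convert_value(s$C0, paste0("species.", s$name, ".C0"), vio),
      m = if (is.null(s$m)) as.integer(s$z) *
            convert_value(s$d, "", vio) else as.numeric(s$m)
    )
  }))
}

apply_species_overrides <- function(tab, sp_list, vio) {
  for (s in sp_list) {
    i <- match(s$name, tab$name)
    if (is.na(i)) {
      vio$add(sprintf("species: '%s' is not a species of this preset", s$name))
      next
    }
    if (!is.null(s$d)) tab$d[i] <- convert_value(s$d, "species.d", vio)
    if (!is.null(s$z)) tab$z[i] <- as.integer(s$z)
    if (!is.null(s$C0)) tab$C0[i] <- convert_value(s$C0, "species.C0", vio)
    tab$m[i] <- if (!is.null(s$m)) as.numeric(s$m) else tab$z[i] * tab$d[i]
  }
  tab
}

#' Re-serialise a configuration
#'
#' Writes the raw parsed configuration back to YAML; a saved and re-loaded
#' configuration is identical to the original.
#'
#' @param config a `pnp_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Build the mesh described by a configuration
#'
#' Either generates the elliptical mesh from `domain.a/b/h` or reads the
#' referenced Gmsh file.
#'
#' @param config a `pnp_config`.
#' @return a [pnp_mesh].
#' @export
config_mesh <- function(config) {
  d <- config$domain
  if (!is.null(d$mesh)) {
    p <- d$mesh
    if (!file.exists(p)) {
      p2 <- file.path(dirname(config$path), d$mesh)
      if (file.exists(p2)) p <- p2 else stop("mesh file not found: ", d$mesh)
    }
    read_mesh_msh(p)
  } else {
    mesh_ellipse(d$a, d$b, d$h)
  }
}

#' @export
print.pnp_config <- function(x, ...) {
  cat(sprintf("pnp run configuration (model '%s')\n", x$kinetics$name))
  cat(sprintf("  domain: %s\n",
              if (!is.null(x$domain$mesh)) x$domain$mesh
              else sprintf("ellipse a = %g, b = %g, h = %g",
                           x$domain$a, x$domain$b, x$domain$h)))
  cat(sprintf("  solver: dt = %g s, T = %g s, eps = %g\n",
              x$solver$dt, x$solver$T, x$solver$eps))
  cat(sprintf("  epsilon = %g, f = %g, phi0 = %g mV\n",
              x$epsilon, x$f, x$phi0))
  invisible(x)
}

#' Run the simulation described by a configuration
#'
#' Convenience wrapper: builds the mesh, runs [simulate()] and (optionally)
#' writes the probe CSV and snapshots under the configured output
#' directory.
#'
#' @param config a `pnp_config`.
#' @param write if `TRUE`, write `probes.csv` (and snapshots when
#'   configured) under `config$output$directory`.
#' @return the `pnp_trajectory`.
#' @export
run_config <- function(config, write = FALSE) {
  mesh <- config_mesh(config)
  outdir <- config$output$directory
  snap <- NULL
  if (write) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (config$solver$snapshot_every > 0L) snap <- outdir
  }
  traj <- simulate(mesh, config$kinetics, config$solver,
                   epsilon = config$epsilon, f = config$f,
                   phi0 = config$phi0, probes = config$probes,
                   snapshot_dir = snap)
  if (write) write_probes_csv(traj, file.path(outdir, "probes.csv"))
  traj
}
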