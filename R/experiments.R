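# Convergence and stability study harnesses.
#
# The convergence error of a run is
#   E_h = dt * sum_i sum_n max_k || Z_i^{n,k+1} - Z_i^{n,k} ||_{L2},
# the time-step-weighted sum over species and steps of the largest Picard
# increment; refining h (with dt tied to h) must drive it down. The
# stability study reruns one model at dt, dt/2, dt/4 and compares final-time
# product fields.

#' Convergence-error metric of a run
#'
#' `E_h = dt * sum` over species and time steps of the maximum-over-Picard
#' iterations L2 increment. A run whose every step converges with zero
#' increment gives 0. Additive over species: computing per species and
#' summing equals the joint computation.
#'
#' @param diagnostics a `pnp_trajectory`, its `$diagnostics` list, or the
#'   steps-by-species matrix of maximal increments itself.
#' @param dt the time step of the run.
#' @return nonnegative scalar `E_h`.
#' @export
convergence_error <- function(diagnostics, dt) {
  m <- if (inherits(diagnostics, "pnp_trajectory")) {
    diagnostics$diagnostics$max_inc
  } else if (is.list(diagnostics) && !is.null(diagnostics$max_inc)) {
    diagnostics$max_inc
  } else if (is.matrix(diagnostics) || is.numeric(diagnostics)) {
    diagnostics
  } else {
    stop("no Picard increment diagnostics found")
  }
  dt * sum(m)
}

#' Mesh-refinement convergence study
#'
#' For each mesh size `h` builds the elliptical mesh, sets `dt = h * T/16`
#' (time step refined proportionally with the space step), runs the model
#' from its constant initial conditions and records `E_h`.
#'
#' @param kinetics a [pnp_kinetics] preset.
#' @param h mesh sizes, by convention in decreasing order.
#' @param T study horizon (s).
#' @param a,b ellipse semi-axes.
#' @param epsilon,f,phi0 electrostatic parameters (see [simulate()]).
#' @param eps,max_picard Picard controls.
#' @return data frame with columns `model, h, dt, nel, E_h, mean_picard`,
#'   sorted by decreasing `h`.
#' @export
convergence_study <- function(kinetics, h = c(0.3, 0.1, 0.05), T = 1,
                              a = 2, b = 1, epsilon = 1e6, f = 0.1,
                              phi0 = -80, eps = 1e-4, max_picard = 50L) {
  h <- sort(h, decreasing = TRUE)
  rows <- lapply(h, function(hi) {
    mesh <- mesh_ellipse(a, b, hi)
    dt <- hi * T / 16
    cfg <- solver_config(dt = dt, T = T, eps = eps, max_picard = max_picard)
    traj <- simulate(mesh, kinetics, cfg, epsilon = epsilon, f = f,
                     phi0 = phi0)
    data.frame(
      model = kinetics$name, h = hi, dt = dt, nel = nrow(mesh$triangles),
      E_h = convergence_error(traj, dt),
      mean_picard = mean(traj$diagnostics$iters)
    )
  })
  do.call(rbind, rows)
}

#' Time-step stability study
#'
#' Runs the model at several time steps to a common final time on one mesh
#' and reports the relative L2 discrepancies of the final product field
#' between consecutive time-step pairs. For an unconditionally stable,
#' first-order-in-time scheme the discrepancies are small and shrink as dt
#' is refined.
#'
#' @param kinetics a [pnp_kinetics] preset.
#' @param dts vector of time steps (any order; sorted decreasing
#'   internally). Each dt not dividing `T` is rounded to the nearest
#'   divisor with a note.
#' @param T common final time (s).
#' @param h mesh size of the single study mesh.
#' @param a,b ellipse semi-axes.
#' @param epsilon,f,phi0,eps,max_picard as in [convergence_study()].
#' @param product index of the product species; defaults to the preset's.
#' @return list with `table` (data frame: `dt1, dt2, rel_discrepancy`),
#'   `fields` (final product nodal fields, one per dt) and `dts` (the
#'   adjusted time steps).
#' @export
stability_study <- function(kinetics, dts, T, h = 0.25, a = 2, b = 1,
                            epsilon = 1e6, f = 0.1, phi0 = -80, eps = 1e-4,
                            max_picard = 50L, product = kinetics$product) {
  dts <- sort(dts, decreasing = TRUE)
  adj <- vapply(dts, function(dt) {
    nst <- max(1L, as.integer(round(T / dt)))
    dta <- T / nst
    if (abs(dta - dt) > 1e-12 * dt) {
      message(sprintf("dt = %g does not divide T = %g; using dt = %g", dt, T, dta))
    }
    dta
  }, numeric(1))
  mesh <- mesh_ellipse(a, b, h)
  fields <- lapply(adj, function(dt) {
    cfg <- solver_config(dt = dt, T = T, eps = eps, max_picard = max_picard)
    traj <- simulate(mesh, kinetics, cfg, epsilon = epsilon, f = f,
                     phi0 = phi0)
    traj$final$C[, product]
  })
  nrm <- function(v) l2_norm(mesh, v)
  tab <- do.call(rbind, lapply(seq_len(length(adj) - 1L), function(i) {
    ref <- nrm(fields[[i + 1L]])
    data.frame(
      dt1 = adj[i], dt2 = adj[i + 1L],
      rel_discrepancy = nrm(fields[[i]] - fields[[i + 1L]]) / ref
    )
  }))
  list(table = tab, fields = fields, dts = adj, mesh = mesh)
}

#' Observed order of accuracy
#'
#' Least-squares slope of `log(error)` against `log(h)` over a refinement
#' ladder.
#'
#' @param h mesh sizes (positive, at least two).
#' @param errors corresponding errors (positive).
#' @return scalar order estimate.
#' @examples
#' observed_order(c(0.2, 0.1, 0.05), c(0.2, 0.1, 0.05)^2) # 2
#' @export
observed_order <- function(h, errors) {
  if (length(h) < 2L || length(errors) != length(h)) {
    stop("need at least two (h, error) pairs")
  }
  if (any(errors <= 0) || any(h <= 0)) {
    stop("orders are undefined for non-positive errors or mesh sizes")
  }
  unname(stats::coef(stats::lm(log(errors) ~ log(h)))[2L])
}

#' Manufactured-solution accuracy study for the Poisson solve
#'
#' On the unit disk with unit permittivity and uniform unit net charge the
#' potential is `phi = (1 - r^2)/4`. The study solves the discrete Poisson
#' problem on a ladder of meshes, measures the nodal L2 error against the
#' closed form, and estimates the observed spatial order (second order for
#' P1 elements).
#'
#' @param h mesh sizes for the ladder.
#' @return list with `table` (data frame `h, error`) and `order`.
#' @export
poisson_order_study <- function(h = c(0.2, 0.1, 0.05)) {
  rows <- lapply(h, function(hi) {
    mesh <- mesh_ellipse(1, 1, hi)
    fes <- fe_structure(mesh, 2)
    rhs <- fe_load(fes, 1)               # unit net charge density
    phi_h <- poisson_solve(fes, mesh$interior, rhs, epsilon = 1)
    r2 <- mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2
    phi_exact <- (1 - r2) / 4
    data.frame(h = hi, error = l2_norm_fes(fes, phi_h - phi_exact))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, order = observed_order(tab$h, tab$error))
}
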