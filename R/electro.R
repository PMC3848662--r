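# Slotboom change of variables and the decoupled Poisson solve.
#
# The substitution Z_i = C_i * exp((m_i/d_i) * phi) symmetrises each
# Nernst-Planck operator into a weighted diffusion operator; the electric
# potential solves a Poisson equation with homogeneous Dirichlet data on the
# membrane, with the net charge density sum_i z_i C_i - f as source.
# Potentials are carried internally in thermal-voltage units so that the
# Boltzmann factors exp(-(m/d) phi) are dimensionless.

#' Slotboom factors for all species
#'
#' Computes the nodal factors `q_i = exp(-(m_i/d_i) * phi)` and their
#' reciprocals `p_i = 1/q_i`; concentrations are reconstructed as
#' `C_i = q_i * Z_i`.
#'
#' @param phi nodal potential in thermal-voltage units.
#' @param species a species table as produced by the kinetics preset
#'   constructors (data frame with columns `d` and `m`), or a numeric vector
#'   of ratios `m/d`.
#' @param clamp exponent clamp bound.
#' @return list with nodes-by-species matrices `q` and `p`.
#' @export
slotboom_factors <- function(phi, species, clamp = 50) {
  ratios <- if (is.data.frame(species)) species$m / species$d else species
  ex <- clamp_exp(outer(phi, ratios), clamp)
  list(q = exp(-ex), p = exp(ex))
}

#' Convert between concentrations and Slotboom variables
#'
#' `direction = "to-C"` multiplies nodewise by `q_i` (reconstruction
#' `C = q Z`); `direction = "to-Z"` divides (transform `Z = p C`). The round
#' trip is the identity to rounding error.
#'
#' @param field nodal vector.
#' @param factors result of [slotboom_factors()].
#' @param species_index which species' factor to use.
#' @param direction `"to-C"` or `"to-Z"`.
#' @return nodal vector.
#' @export
slotboom_transform <- function(field, factors, species_index,
                               direction = c("to-C", "to-Z")) {
  direction <- match.arg(direction)
  q <- factors$q[, species_index]
  if (direction == "to-C") field * q else field / q
}

# Interior-block Poisson solve: eps * Q_YY zeta_Y = rhs_Y, zeta = 0 on the
# membrane. `chol` may carry a precomputed Cholesky factor of Q_YY.
poisson_solve <- function(fes, interior, rhs, epsilon, Q = NULL, chol = NULL) {
  m <- fes$m
  if (length(interior) == 0L) {
    stop("degenerate mesh: no interior nodes, the Poisson system is empty")
  }
  zeta <- numeric(m)
  if (is.null(chol)) {
    if (is.null(Q)) Q <- fe_stiffness(fes)
    QYY <- methods::as(Q[interior, interior, drop = FALSE], "CsparseMatrix")
    chol <- Matrix::Cholesky(Matrix::forceSymmetric(QYY), LDL = FALSE)
  }
  zeta[interior] <- as.vector(Matrix::solve(chol, rhs[interior] / epsilon))
  zeta
}

#' Solve the discrete Poisson equation for the potential
#'
#' Solves `eps * Q_YY zeta_Y = [sum_i z_i M_i xi_i - beta]_Y` for the
#' interior potential values, with zero boundary values on the membrane.
#' The right-hand side uses the current Slotboom variables and factors, i.e.
#' the reconstructed net charge density `sum_i z_i C_i - f`.
#'
#' @param mesh a [pnp_mesh].
#' @param state a list with elements `zeta` (nodal potential used for the
#'   mass-matrix weights) and `xi` (nodes-by-species Slotboom variables),
#'   e.g. a [initialize_state()] result.
#' @param species species table (columns `d`, `m`, `z`).
#' @param epsilon permittivity (simulation units, positive).
#' @param f fixed-charge density (constant or function of `x, y`).
#' @param degree quadrature degree.
#' @param clamp exponent clamp bound.
#' @return nodal potential vector (thermal-voltage units), zero on the
#'   membrane; the interior residual is at solver precision.
#' @export
solve_potential <- function(mesh, state, species, epsilon, f = 0,
                            degree = 2, clamp = 50) {
  if (epsilon <= 0) stop("`epsilon` must be positive")
  fes <- fe_structure(mesh, degree)
  rhs <- charge_rhs(fes, state$zeta, state$xi, species$m / species$d,
                    species$z, f, clamp)
  poisson_solve(fes, mesh$interior, rhs, epsilon)
}

# rhs_i = sum_j z_j (M_j xi_j)_i - beta_i, evaluated as one load with the
# quadrature-point integrand sum_j z_j exp(-(m_j/d_j) phi) Z_j - f.
charge_rhs <- function(fes, zeta, xi, ratios, z, f, clamp = 50) {
  xi <- as.matrix(xi)
  gq <- matrix(0, fes$nel, fes$nq)
  for (j in seq_along(z)) {
    if (z[j] == 0) next
    wq <- slotboom_weight_quad(fes, zeta, ratios[j], clamp)
    gq <- gq + z[j] * wq * interp_quad(fes, xi[, j])
  }
  if (is.function(f)) {
    gq <- gq - matrix(f(as.vector(fes$qx), as.vector(fes$qy)), fes$nel, fes$nq)
  } else if (f != 0) {
    gq <- gq - f
  }
  fe_load(fes, gq)
}
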