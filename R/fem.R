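# P1 finite-element assembly.
#
# All matrices of the discrete system are sums of per-element integrals of
# the form  integral_e w(x) * N_l * N_s  (weighted mass),
#           integral_e w(x) * grad N_l . grad N_s  (weighted stiffness),
#           integral_e g(x) * N_s  (load),
# where w(x) = exp(-(m/d) * phi_h(x)) is the Slotboom weight. The exponent is
# evaluated by interpolating the nodal potential to the quadrature points
# before exponentiation, and clamped to a configurable range to guard against
# overflow for unscaled potentials (a counter records clamp events).

.pnp_env <- new.env(parent = emptyenv())
.pnp_env$clamp_count <- 0L

clamp_exp <- function(x, clamp = 50) {
  n <- sum(x > clamp | x < -clamp)
  if (n > 0L) .pnp_env$clamp_count <- .pnp_env$clamp_count + n
  pmin(pmax(x, -clamp), clamp)
}

#' Exponent clamp counter
#'
#' Number of Slotboom exponent evaluations clamped to the safe range since
#' the counter was last reset. The reference runs keep exponents well inside
#' the range, so a nonzero count flags an unscaled potential.
#'
#' @param reset if `TRUE`, zero the counter after reading.
#' @return integer count.
#' @export
clamp_count <- function(reset = FALSE) {
  n <- .pnp_env$clamp_count
  if (reset) .pnp_env$clamp_count <- 0L
  n
}

# Symmetric triangle quadrature rules in barycentric coordinates.
# Weights sum to 1 (scaled by the element area at use sites).
# degree 2: edge-midpoint rule, exact for quadratics (hence for products of
# two P1 basis functions); degree 4: 6-point rule for smooth exponential
# weights.
tri_quadrature <- function(degree = 2) {
  if (degree <= 2) {
    list(
      lambda = rbind(c(.5, .5, 0), c(0, .5, .5), c(.5, 0, .5)),
      w = rep(1 / 3, 3)
    )
  } else {
    a1 <- 0.445948490915965; w1 <- 0.223381589678011
    a2 <- 0.091576213509771; w2 <- 0.109951743655322
    list(
      lambda = rbind(
        c(1 - 2 * a1, a1, a1), c(a1, 1 - 2 * a1, a1), c(a1, a1, 1 - 2 * a1),
        c(1 - 2 * a2, a2, a2), c(a2, 1 - 2 * a2, a2), c(a2, a2, 1 - 2 * a2)
      ),
      w = c(w1, w1, w1, w2, w2, w2)
    )
  }
}

# Precomputed element geometry + quadrature for repeated assembly.
fe_structure <- function(mesh, degree = 2) {
  tri <- mesh$triangles
  nd <- mesh$nodes
  x1 <- nd[tri[, 1L], 1L]; y1 <- nd[tri[, 1L], 2L]
  x2 <- nd[tri[, 2L], 1L]; y2 <- nd[tri[, 2L], 2L]
  x3 <- nd[tri[, 3L], 1L]; y3 <- nd[tri[, 3L], 2L]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  inv2A <- 1 / (2 * area)
  # constant P1 gradients: grad N_k = (b_k, c_k) / (2A)
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) * inv2A
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) * inv2A
  q <- tri_quadrature(degree)
  m <- nrow(nd)
  # shared sparsity pattern of all assembled operators (mesh adjacency):
  # precompute the map from the 9 per-element entries to the upper-triangle
  # slots of a symmetric template, so repeated assembly is a single
  # permute-and-accumulate pass
  pairs <- cbind(rep(1:3, times = 3), rep(1:3, each = 3))
  i9 <- as.vector(tri[, pairs[, 1L]])
  j9 <- as.vector(tri[, pairs[, 2L]])
  template <- Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = i9, j = j9, x = 0, dims = c(m, m))
  )
  colidx <- rep.int(seq_len(m), diff(template@p))
  tkey <- (colidx - 1) * m + (template@i + 1)
  slot <- match((pmax(i9, j9) - 1) * m + pmin(i9, j9), tkey)
  # each off-diagonal entry is visited from both (i,j) and (j,i)
  sym_w <- ifelse(i9 == j9, 1, 0.5)
  sord <- order(slot)
  sends <- cumsum(tabulate(slot, length(template@x)))
  # load-vector accumulation map (3 entries per element onto the nodes)
  l3 <- as.vector(tri)
  lord <- order(l3)
  lends <- cumsum(tabulate(l3, m))
  list(
    mesh = mesh, tri = tri, m = m, nel = nrow(tri),
    area = area, gx = gx, gy = gy,
    lambda = q$lambda, w = q$w, nq = length(q$w),
    qx = cbind(x1, x2, x3) %*% t(q$lambda),
    qy = cbind(y1, y2, y3) %*% t(q$lambda),
    pairs = pairs, template = template, sym_w = sym_w,
    sord = sord, sends = sends, lord = lord, lends = lends
  )
}

# Accumulate a permuted value vector into per-group sums by cumsum
# differencing (groups are contiguous after the precomputed ordering and
# every group is nonempty).
acc_groups <- function(v, ord, ends) {
  cs <- cumsum(v[ord])
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

# Fill the shared symmetric template from per-element 9-column value blocks.
fe_fill <- function(fes, vals) {
  M <- fes$template
  M@x <- acc_groups(as.vector(vals) * fes$sym_w, fes$sord, fes$sends)
  M
}

# Interpolate a nodal P1 field to the quadrature points: nel x nq matrix.
interp_quad <- function(fes, v) {
  vv <- matrix(v[fes$tri], fes$nel, 3L)
  vv %*% t(fes$lambda)
}

# Weighted mass matrix from an arbitrary quadrature-point weight (nel x nq,
# or a scalar). This is the workhorse behind both the Slotboom-weighted mass
# matrices and the implicit (current-iterate) reaction terms.
fe_mass <- function(fes, wq = 1) {
  if (length(wq) == 1L) wq <- matrix(wq, fes$nel, fes$nq)
  lam <- fes$lambda
  idx <- fes$pairs
  vals <- matrix(0, fes$nel, 9L)
  for (p in 1:9) {
    l <- idx[p, 1L]; s <- idx[p, 2L]
    vals[, p] <- fes$area * (wq %*% (fes$w * lam[, l] * lam[, s]))
  }
  fe_fill(fes, vals)
}

# Weighted stiffness: gradients are constant per element, so the weight only
# enters through its element average under the quadrature rule.
fe_stiffness <- function(fes, wq = 1, d = 1) {
  if (length(wq) == 1L) {
    wbar <- rep(wq, fes$nel)
  } else {
    wbar <- as.vector(wq %*% fes$w)
  }
  idx <- fes$pairs
  vals <- matrix(0, fes$nel, 9L)
  for (p in 1:9) {
    l <- idx[p, 1L]; s <- idx[p, 2L]
    g <- fes$gx[, l] * fes$gx[, s] + fes$gy[, l] * fes$gy[, s]
    vals[, p] <- d * fes$area * wbar * g
  }
  fe_fill(fes, vals)
}

# Load vector from a quadrature-point integrand g (nel x nq or scalar).
fe_load <- function(fes, gq) {
  if (length(gq) == 1L) gq <- matrix(gq, fes$nel, fes$nq)
  vals <- matrix(0, fes$nel, 3L)
  for (s in 1:3) {
    vals[, s] <- fes$area * (gq %*% (fes$w * fes$lambda[, s]))
  }
  acc_groups(as.vector(vals), fes$lord, fes$lends)
}

slotboom_weight_quad <- function(fes, phi, ratio, clamp = 50) {
  if (is.null(phi) || ratio == 0 || all(phi == 0)) {
    matrix(1, fes$nel, fes$nq)
  } else {
    exp(clamp_exp(-ratio * interp_quad(fes, phi), clamp))
  }
}

#' Assemble the Slotboom-weighted mass matrix
#'
#' Entries are elementwise integrals of
#' `exp(-ratio * phi_h) * N_l * N_s`, with `ratio = m/d` the mobility to
#' diffusion ratio of the species. With `phi = 0` this is the standard P1
#' mass matrix.
#'
#' @param mesh a [pnp_mesh].
#' @param phi nodal potential (thermal-voltage units); `NULL` means zero.
#' @param ratio mobility/diffusion ratio `m/d` of the species.
#' @param degree quadrature degree, 2 (edge midpoints) or 4 (6-point).
#' @param clamp exponent clamp bound.
#' @return sparse symmetric matrix (`Matrix::dgCMatrix`).
#' @export
assemble_weighted_mass <- function(mesh, phi = NULL, ratio = 0, degree = 2,
                                   clamp = 50) {
  fes <- fe_structure(mesh, degree)
  fe_mass(fes, slotboom_weight_quad(fes, phi, ratio, clamp))
}

#' Assemble the Slotboom-weighted stiffness matrix
#'
#' Entries are `d` times elementwise integrals of
#' `exp(-ratio * phi_h) * grad N_l . grad N_s`. Rows sum to zero because the
#' P1 shape-function gradients sum to the zero vector, which is what makes
#' the scheme conserve mass discretely.
#'
#' @inheritParams assemble_weighted_mass
#' @param d diffusion coefficient (positive).
#' @return sparse symmetric matrix with zero row sums.
#' @export
assemble_weighted_stiffness <- function(mesh, phi = NULL, d = 1, ratio = 0,
                                        degree = 2, clamp = 50) {
  if (d <= 0) stop("`d` must be positive")
  fes <- fe_structure(mesh, degree)
  fe_stiffness(fes, slotboom_weight_quad(fes, phi, ratio, clamp), d)
}

#' Assemble the Laplace stiffness matrix
#'
#' The unweighted P1 stiffness matrix of the Poisson operator; positive
#' semidefinite, and positive definite when restricted to interior rows and
#' columns.
#'
#' @param mesh a [pnp_mesh].
#' @return sparse symmetric matrix.
#' @export
assemble_laplace <- function(mesh) {
  assemble_weighted_stiffness(mesh, phi = NULL, d = 1, ratio = 0)
}

#' Assemble the fixed-charge load vector
#'
#' Entry `i` is the integral of `f * N_i`; for constant `f` this is `f`
#' times one third of the area of the triangles touching node `i`, and the
#' entries sum to `f` times the domain area.
#'
#' @param mesh a [pnp_mesh].
#' @param f fixed-charge density: a constant or a function `f(x, y)`
#'   (vectorised) evaluated at quadrature points.
#' @param degree quadrature degree.
#' @return numeric nodal vector.
#' @export
assemble_charge_load <- function(mesh, f, degree = 2) {
  fes <- fe_structure(mesh, degree)
  gq <- if (is.function(f)) {
    matrix(f(as.vector(fes$qx), as.vector(fes$qy)), fes$nel, fes$nq)
  } else {
    f
  }
  fe_load(fes, gq)
}

#' Assemble a reaction load vector
#'
#' Entry `i` is the elementwise integral of
#' `F_s(C_1, ..., C_Ns) * N_i`, the reaction rate of species
#' `species_index` evaluated at the concentrations reconstructed at
#' quadrature points as `C_j = exp(-ratio_j * phi_h) * Z_j` from the nodal
#' Slotboom variables.
#'
#' @param mesh a [pnp_mesh].
#' @param rate function mapping a points-by-species concentration matrix to
#'   a matrix of per-species rates (a [pnp_kinetics]`$rate` works).
#' @param phi nodal potential (thermal-voltage units) at the evaluation time.
#' @param Z nodes-by-species matrix of nodal Slotboom variables.
#' @param ratios per-species mobility/diffusion ratios `m/d`.
#' @param species_index which species' rate to integrate.
#' @param degree quadrature degree.
#' @param clamp exponent clamp bound.
#' @return numeric nodal vector.
#' @export
assemble_reaction_load <- function(mesh, rate, phi, Z, ratios, species_index,
                                   degree = 2, clamp = 50) {
  Z <- as.matrix(Z)
  fes <- fe_structure(mesh, degree)
  ns <- ncol(Z)
  C <- matrix(0, fes$nel * fes$nq, ns)
  for (j in seq_len(ns)) {
    wq <- slotboom_weight_quad(fes, phi, ratios[j], clamp)
    C[, j] <- as.vector(wq * interp_quad(fes, Z[, j]))
  }
  Fq <- rate(C)
  fq <- if (is.matrix(Fq)) Fq[, species_index] else Fq
  if (any(!is.finite(fq))) {
    bad <- which(!is.finite(matrix(fq, fes$nel, fes$nq)), arr.ind = TRUE)
    stop(sprintf(
      "non-finite reaction rate for species %d on element %d",
      species_index, bad[1L, 1L]
    ))
  }
  fe_load(fes, matrix(fq, fes$nel, fes$nq))
}

#' Discrete L2 norm of a nodal field
#'
#' `sqrt(t(v) M v)` with `M` the (unweighted) P1 mass matrix; the norm used
#' by the Picard stopping criterion and the convergence-error metric.
#'
#' @param mesh a [pnp_mesh].
#' @param v numeric nodal vector.
#' @return nonnegative scalar, zero iff `v` is zero.
#' @export
l2_norm <- function(mesh, v) {
  fes <- fe_structure(mesh, 2)
  l2_norm_fes(fes, v)
}

l2_norm_fes <- function(fes, v) {
  vq <- interp_quad(fes, v)
  sqrt(max(0, sum(fes$area * ((vq * vq) %*% fes$w))))
}

#' Export a sparse matrix in MatrixMarket format
#'
#' Debugging aid for inspecting assembled operators outside R.
#'
#' @param mat a sparse `Matrix`.
#' @param path output file path (`.mtx`).
#' @return `path`, invisibly.
#' @export
write_mtx <- function(mat, path) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), path)
  invisible(path)
}
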