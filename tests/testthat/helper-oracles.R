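# Independent oracles used across the test files. These deliberately do not
# share code with the package internals: the scalar Picard oracle below
# re-derives the per-model backward-Euler linearisation by hand, and the
# high-order quadrature oracle integrates on the reference triangle through
# a Duffy-transformed tensor Gauss rule.

# unit right triangle (0,0), (1,0), (0,1)
unit_triangle <- function() {
  pnp_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
}

# Gauss-Legendre nodes/weights on [0,1] by Golub-Welsch
gauss01 <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = (e$vectors[1, ]^2))
}

# integral over the unit right triangle of f(x, y), essentially exact for
# smooth f (Duffy transform of a 32x32 tensor Gauss rule)
tri_integral_oracle <- function(f, n = 32) {
  g <- gauss01(n)
  acc <- 0
  for (i in seq_len(n)) {
    u <- g$x[i]
    x <- u
    y <- (1 - u) * g$x            # v scaled into the triangle
    acc <- acc + g$w[i] * (1 - u) * sum(g$w * f(x, y))
  }
  acc
}

# Scalar (well-mixed) backward-Euler/Picard oracles replicating the
# per-model linearisation for spatially uniform, uncharged runs. The Picard
# loop stops on the same criterion as the PDE solver: increment times
# sqrt(domain area) below eps.
scalar_basic_step <- function(c, dt, p, eps_l2, sqrt_area, max_iter = 50) {
  c1 <- c[1]                                   # no reaction term
  ck <- c[2]
  repeat {
    g <- p$k2 * p$C10 / (p$kM + ck)
    cnew <- c[2] / (1 + dt * g)
    inc <- abs(cnew - ck) * sqrt_area
    ck <- cnew
    if (inc < eps_l2) break
    max_iter <- max_iter - 1
    if (max_iter <= 0) break
  }
  v <- p$k2 * p$C10 * ck / (p$kM + ck)
  c3 <- c[3] + dt * v
  c(c1, ck, c3)
}

scalar_suicide_step <- function(c, dt, p, eps_l2, sqrt_area, max_iter = 50) {
  cur <- c
  repeat {
    prev <- cur
    cur[1] <- (c[1] + dt * (p$km1 * prev[3] + p$k3 * prev[4])) /
      (1 + dt * p$k1 * prev[2])
    cur[2] <- (c[2] + dt * p$km1 * prev[3]) / (1 + dt * p$k1 * cur[1])
    cur[3] <- (c[3] + dt * p$k1 * cur[1] * cur[2]) /
      (1 + dt * (p$km1 + p$k2))
    cur[4] <- (c[4] + dt * p$k2 * cur[3]) / (1 + dt * (p$k3 + p$k4))
    cur[5] <- c[5] + dt * p$k4 * cur[4]
    cur[6] <- c[6] + dt * p$k3 * cur[4]
    if (sum(abs(cur - prev)) * sqrt_area < eps_l2) break
    max_iter <- max_iter - 1
    if (max_iter <= 0) break
  }
  cur
}

scalar_cooperative_step <- function(c, dt, p, eps_l2, sqrt_area,
                                    max_iter = 50) {
  cur <- c
  repeat {
    prev <- cur
    cur[1] <- (c[1] + dt * (p$km1 + p$k2) * prev[3]) /
      (1 + dt * p$k1 * prev[2])
    cur[2] <- (c[2] + dt * (p$km1 * prev[3] + p$km3 * prev[4])) /
      (1 + dt * (p$k1 * cur[1] + p$k3 * prev[3]))
    cur[3] <- (c[3] + dt * (p$k1 * cur[1] * cur[2] +
                              (p$km3 + p$k4) * prev[4])) /
      (1 + dt * (p$km1 + p$k2 + p$k3 * cur[2]))
    cur[4] <- (c[4] + dt * p$k3 * cur[2] * cur[3]) /
      (1 + dt * (p$km3 + p$k4))
    cur[5] <- c[5] + dt * (p$k2 * cur[3] + p$k4 * cur[4])
    if (sum(abs(cur - prev)) * sqrt_area < eps_l2) break
    max_iter <- max_iter - 1
    if (max_iter <= 0) break
  }
  cur
}

# neutral variant of a species table (no valence, no mobility): makes the
# PDE run spatially uniform so it can be compared with the scalar oracle
neutralize <- function(species) {
  species$z <- 0L
  species$m <- 0
  species
}
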