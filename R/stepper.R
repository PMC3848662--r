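# Implicit-Euler time integration of the Slotboom-transformed system.
#
# One step, following the per-model resolution order:
#   1. potential solve from the lagged charge density (q^n, Z^n),
#   2. Slotboom factor update q^{n+1} = exp(-(m/d) phi^{n+1}),
#   3. species solves (A^{n+1} + dt R^{n+1}) Z^{n+1} = A^n Z^n + dt S^{n+1},
# with the nonlinear reaction loads handled by the model's Picard pattern:
# for the basic model only the substrate is iterated (own factor implicit,
# denominator lagged); for the mass-action models all species are swept in
# order inside one Picard loop, stopping when the summed L2 increment drops
# below eps.

#' Solver configuration
#'
#' @param dt time step (s, positive).
#' @param T final time (s, `>= dt`).
#' @param eps Picard stopping tolerance on the (summed) L2 increment.
#' @param max_picard iteration cap per time step.
#' @param degree quadrature degree for the exponential weights (2 or 4).
#' @param V_T thermal voltage (mV) used to scale potentials internally.
#' @param clamp Slotboom exponent clamp bound.
#' @param on_nonconvergence `"warn"` (accept the last iterate and flag the
#'   step) or `"abort"`.
#' @param snapshot_every write a field snapshot every this many steps
#'   (0 disables).
#' @return a `pnp_solver_config` list.
#' @export
solver_config <- function(dt, T, eps = 1e-4, max_picard = 50L, degree = 2,
                          V_T = 25.693, clamp = 50,
                          on_nonconvergence = c("warn", "abort"),
                          snapshot_every = 0L) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  if (!is.finite(T) || T < dt) stop("`T` must be at least `dt`")
  if (eps <= 0) stop("`eps` must be positive")
  if (max_picard < 1) stop("`max_picard` must be at least 1")
  structure(
    list(dt = dt, T = T, eps = eps, max_picard = as.integer(max_picard),
         degree = degree, V_T = V_T, clamp = clamp,
         on_nonconvergence = match.arg(on_nonconvergence),
         snapshot_every = as.integer(snapshot_every)),
    class = "pnp_solver_config"
  )
}

#' Initialise the simulation state
#'
#' Sets the initial potential (interior nodes at `phi0/V_T` thermal units,
#' membrane nodes at 0 per the Dirichlet condition) and the initial Slotboom
#' variables `Z_i(0) = C_i(0) * p_i(0)`.
#'
#' @param mesh a [pnp_mesh].
#' @param species species table (columns `d, m, z, C0`).
#' @param config a [solver_config()].
#' @param phi0 initial interior potential in mV.
#' @return a `pnp_state` list with step index `n`, time `t`, nodal potential
#'   `zeta` (thermal units) and the nodes-by-species matrix `xi` of Slotboom
#'   variables.
#' @export
initialize_state <- function(mesh, species, config, phi0 = -80) {
  if (any(species$C0 < 0)) {
    stop("initial concentrations must be nonnegative")
  }
  m <- nrow(mesh$nodes)
  zeta <- numeric(m)
  zeta[mesh$interior] <- phi0 / config$V_T
  fac <- slotboom_factors(zeta, species, config$clamp)
  C0 <- matrix(rep(species$C0, each = m), m)
  structure(
    list(n = 0L, t = 0, zeta = zeta, xi = C0 * fac$p, Amats = NULL,
         diag = NULL),
    class = "pnp_state"
  )
}

# Shared per-run context: FE structure, Poisson factorisation, species
# index maps (species with equal m/d share their weighted matrices).
step_context <- function(mesh, species, config) {
  fes <- fe_structure(mesh, config$degree)
  Q <- fe_stiffness(fes)
  interior <- mesh$interior
  QYY <- methods::as(Q[interior, interior, drop = FALSE], "CsparseMatrix")
  ratios <- species$m / species$d
  ur <- unique(ratios)
  # symbolic factorisation shared by every species solve (all system
  # matrices live on the mesh-adjacency pattern)
  symb <- Matrix::Cholesky(Matrix::forceSymmetric(fe_mass(fes) + fe_stiffness(fes)),
                           LDL = FALSE)
  list(
    fes = fes, interior = interior, symb = symb,
    cholQ = Matrix::Cholesky(Matrix::forceSymmetric(QYY), LDL = FALSE),
    ratios = ratios, uratios = ur, umap = match(ratios, ur),
    z = species$z, d = species$d, ns = nrow(species)
  )
}

solve_spd <- function(LHS, rhs, symb = NULL) {
  if (!methods::is(LHS, "dsCMatrix")) LHS <- Matrix::forceSymmetric(LHS)
  if (is.null(symb)) {
    return(as.vector(Matrix::solve(LHS, rhs)))
  }
  ch <- Matrix::update(symb, LHS, mult = 0)
  as.vector(Matrix::solve(ch, rhs))
}

#' Advance the state by one time step
#'
#' Performs one implicit-Euler step in the printed order: potential solve
#' from the lagged charge density, Slotboom factor update, then the species
#' solves with the model's Picard linearisation.
#'
#' @param state a `pnp_state` (from [initialize_state()] or a previous
#'   `advance()`).
#' @param mesh a [pnp_mesh].
#' @param kinetics a [pnp_kinetics] preset.
#' @param config a [solver_config()].
#' @param epsilon permittivity (simulation units).
#' @param f fixed-charge density.
#' @param species species table; defaults to the kinetics preset's.
#' @param ctx internal per-run context (built automatically).
#' @return the state at `t + dt`, with Picard diagnostics in `$diag`:
#'   iteration count, per-species max L2 increment, convergence flag, and
#'   the count of nodes where a reconstructed concentration dropped below
#'   -1e-8.
#' @export
advance <- function(state, mesh, kinetics, config, epsilon = 1e6, f = 0.1,
                    species = kinetics$species, ctx = NULL) {
  if (is.null(ctx)) ctx <- step_context(mesh, species, config)
  fes <- ctx$fes
  dt <- config$dt
  clamp <- config$clamp
  ns <- ctx$ns
  xi_n <- state$xi

  # 1. potential from the lagged charge density
  rhs <- charge_rhs(fes, state$zeta, xi_n, ctx$ratios, ctx$z, f, clamp)
  zeta1 <- poisson_solve(fes, ctx$interior, rhs, epsilon, chol = ctx$cholQ)

  # 2. Slotboom weights at the new potential (shared across equal m/d)
  nur <- length(ctx$uratios)
  wq_new <- vector("list", nur)
  Anew <- vector("list", nur)
  Swnew <- vector("list", nur)
  Aold <- state$Amats
  need_old <- is.null(Aold)
  if (need_old) Aold <- vector("list", nur)
  for (u in seq_len(nur)) {
    wq_new[[u]] <- slotboom_weight_quad(fes, zeta1, ctx$uratios[u], clamp)
    Anew[[u]] <- fe_mass(fes, wq_new[[u]])
    Swnew[[u]] <- fe_stiffness(fes, wq_new[[u]], 1)
    if (need_old) {
      Aold[[u]] <- fe_mass(
        fes, slotboom_weight_quad(fes, state$zeta, ctx$uratios[u], clamp)
      )
    }
  }

  LHSbase <- vector("list", ns)
  rhs_base <- vector("list", ns)
  for (i in seq_len(ns)) {
    u <- ctx$umap[i]
    LHSbase[[i]] <- Anew[[u]] + (dt * ctx$d[i]) * Swnew[[u]]
    rhs_base[[i]] <- as.vector(Aold[[u]] %*% xi_n[, i])
  }

  max_inc <- numeric(ns)
  converged <- TRUE
  iters <- 0L

  if (kinetics$scheme == "basic") {
    p <- kinetics$params
    Z <- xi_n
    Z[, 1L] <- solve_spd(LHSbase[[1L]], rhs_base[[1L]], ctx$symb)
    # substrate: own factor implicit, Michaelis denominator lagged
    u2 <- ctx$umap[2L]
    q2q <- wq_new[[u2]]
    Zk <- xi_n[, 2L]
    repeat {
      iters <- iters + 1L
      C2k <- q2q * interp_quad(fes, Zk)
      G <- fe_mass(fes, p$k2 * p$C10 * q2q / (p$kM + C2k))
      Znew <- solve_spd(LHSbase[[2L]] + dt * G, rhs_base[[2L]], ctx$symb)
      inc <- l2_norm_fes(fes, Znew - Zk)
      max_inc[2L] <- max(max_inc[2L], inc)
      Zk <- Znew
      if (inc < config$eps) break
      if (iters >= config$max_picard) {
        converged <- FALSE
        break
      }
    }
    Z[, 2L] <- Zk
    C2q <- q2q * interp_quad(fes, Zk)
    vload <- fe_load(fes, p$k2 * p$C10 * C2q / (p$kM + C2q))
    Z[, 3L] <- solve_spd(LHSbase[[3L]], rhs_base[[3L]] + dt * vload, ctx$symb)
  } else {
    # Gauss-Seidel species sweep over the mass-action terms
    terms <- kinetics$terms
    Zcur <- xi_n
    Cq <- vector("list", ns)
    for (i in seq_len(ns)) {
      Cq[[i]] <- wq_new[[ctx$umap[i]]] * interp_quad(fes, Zcur[, i])
    }
    repeat {
      iters <- iters + 1L
      Zprev <- Zcur
      CqPrev <- Cq
      for (i in seq_len(ns)) {
        if (length(terms[[i]]) == 0L) {
          if (iters == 1L) {
            Zcur[, i] <- solve_spd(LHSbase[[i]], rhs_base[[i]], ctx$symb)
            Cq[[i]] <- wq_new[[ctx$umap[i]]] * interp_quad(fes, Zcur[, i])
          }
          next
        }
        lhswq <- NULL
        loadgq <- NULL
        for (tm in terms[[i]]) {
          pwv <- tm$powers
          own <- pwv[i]
          fac <- NULL
          for (j in which(pwv > 0L)) {
            if (j == i) next
            fj <- if (pwv[j] == 1L) Cq[[j]] else Cq[[j]]^pwv[j]
            fac <- if (is.null(fac)) fj else fac * fj
          }
          if (tm$coef < 0 && own >= 1L) {
            wqt <- (-tm$coef) * wq_new[[ctx$umap[i]]]
            if (own > 1L) wqt <- wqt * CqPrev[[i]]^(own - 1L)
            if (!is.null(fac)) wqt <- wqt * fac
            lhswq <- if (is.null(lhswq)) wqt else lhswq + wqt
          } else {
            gqt <- if (is.null(fac)) tm$coef else tm$coef * fac
            if (own >= 1L) gqt <- gqt * CqPrev[[i]]^own
            loadgq <- if (is.null(loadgq)) gqt else loadgq + gqt
          }
        }
        LHS <- LHSbase[[i]]
        if (!is.null(lhswq)) LHS <- LHS + dt * fe_mass(fes, lhswq)
        rr <- rhs_base[[i]]
        if (!is.null(loadgq)) rr <- rr + dt * fe_load(fes, loadgq)
        Zcur[, i] <- solve_spd(LHS, rr, ctx$symb)
        Cq[[i]] <- wq_new[[ctx$umap[i]]] * interp_quad(fes, Zcur[, i])
      }
      inc <- vapply(seq_len(ns),
                    function(i) l2_norm_fes(fes, Zcur[, i] - Zprev[, i]),
                    numeric(1))
      max_inc <- pmax(max_inc, inc)
      if (sum(inc) < config$eps) break
      if (iters >= config$max_picard) {
        converged <- FALSE
        break
      }
    }
    Z <- Zcur
  }

  if (!converged) {
    msg <- sprintf(
      "Picard iteration did not reach eps = %g in %d iterations at t = %g (model '%s')",
      config$eps, config$max_picard, state$t + dt, kinetics$name
    )
    if (config$on_nonconvergence == "abort") stop(msg) else warning(msg)
  }

  # reconstructed-concentration positivity check
  qnod <- exp(-clamp_exp(outer(zeta1, ctx$ratios), clamp))
  neg <- sum(qnod * Z < -1e-8)

  structure(
    list(n = state$n + 1L, t = state$t + dt, zeta = zeta1, xi = Z,
         Amats = Anew,
         diag = list(iters = iters, max_inc = max_inc,
                     converged = converged, negative_nodes = neg)),
    class = "pnp_state"
  )
}

#' Run a full simulation
#'
#' Integrates the coupled Nernst-Planck/Poisson system from `t = 0` to
#' `T` in exactly `ceiling(T/dt)` implicit-Euler steps, recording
#' concentration probes and Picard diagnostics.
#'
#' @inheritParams advance
#' @param probes matrix of probe points (one row per point); the default is
#'   the cell centre. Each probe records the concentration `C_i = q_i Z_i`
#'   at the nearest node.
#' @param phi0 initial interior potential (mV).
#' @param snapshot_dir if non-`NULL` and `config$snapshot_every > 0`, VTK
#'   snapshots are written there with a CSV series index.
#' @param verbose if `TRUE`, log one line per step (time, Picard iteration
#'   count, largest increment).
#' @return a `pnp_trajectory`: list with `probes` (data frame: `time`, one
#'   column per species per probe in muM, `phi_mV`, `picard_iters`),
#'   `diagnostics` (`max_inc` steps-by-species matrix of maximal Picard L2
#'   increments, iteration counts, convergence flags, negative-node counts),
#'   `final` (nodal `zeta`, `xi`, concentrations `C`), and the run metadata.
#' @export
simulate <- function(mesh, kinetics, config, epsilon = 1e6, f = 0.1,
                     phi0 = -80, probes = rbind(c(0, 0)),
                     species = kinetics$species, snapshot_dir = NULL,
                     verbose = FALSE) {
  ctx <- step_context(mesh, species, config)
  state <- initialize_state(mesh, species, config, phi0)
  nsteps <- as.integer(ceiling(config$T / config$dt))
  ns <- ctx$ns
  probes <- if (is.matrix(probes)) probes else rbind(probes)
  pidx <- apply(probes, 1L, function(p) nearest_node(mesh, p))
  np <- length(pidx)

  probe_row <- function(state) {
    qn <- exp(-clamp_exp(outer(state$zeta, ctx$ratios), config$clamp))
    C <- qn * state$xi
    vals <- as.vector(t(C[pidx, , drop = FALSE]))
    c(state$t, vals, state$zeta[pidx[1L]] * config$V_T,
      if (is.null(state$diag)) 0L else state$diag$iters)
  }

  rec <- matrix(0, nsteps + 1L, 1L + ns * np + 2L)
  rec[1L, ] <- probe_row(state)
  max_inc <- matrix(0, nsteps, ns)
  iters <- integer(nsteps)
  converged <- logical(nsteps)
  neg_nodes <- integer(nsteps)

  snap_every <- config$snapshot_every
  do_snap <- !is.null(snapshot_dir) && snap_every > 0L
  snap_files <- character(0)
  snap_times <- numeric(0)
  if (do_snap) {
    dir.create(snapshot_dir, recursive = TRUE, showWarnings = FALSE)
    fn <- file.path(snapshot_dir, "snapshot_000000.vtk")
    write_vtk(fn, mesh, state_fields(state, species, config))
    snap_files <- fn; snap_times <- 0
  }

  for (n in seq_len(nsteps)) {
    state <- advance(state, mesh, kinetics, config, epsilon = epsilon,
                     f = f, species = species, ctx = ctx)
    rec[n + 1L, ] <- probe_row(state)
    max_inc[n, ] <- state$diag$max_inc
    iters[n] <- state$diag$iters
    converged[n] <- state$diag$converged
    neg_nodes[n] <- state$diag$negative_nodes
    if (verbose) {
      message(sprintf("step %d  t = %.6g  picard = %d  max_inc = %.3e",
                      n, state$t, state$diag$iters,
                      max(state$diag$max_inc)))
    }
    if (do_snap && (n %% snap_every == 0L || n == nsteps)) {
      fn <- file.path(snapshot_dir, sprintf("snapshot_%06d.vtk", n))
      write_vtk(fn, mesh, state_fields(state, species, config))
      snap_files <- c(snap_files, fn)
      snap_times <- c(snap_times, state$t)
    }
  }

  cn <- if (np == 1L) species$name else {
    as.vector(vapply(seq_len(np), function(p) paste0(species$name, "_p", p),
                     character(ns)))
  }
  pr <- as.data.frame(rec)
  names(pr) <- c("time", cn, "phi_mV", "picard_iters")

  if (do_snap) {
    utils::write.csv(
      data.frame(file = basename(snap_files), time = snap_times),
      file.path(snapshot_dir, "series_index.csv"), row.names = FALSE
    )
  }

  qn <- exp(-clamp_exp(outer(state$zeta, ctx$ratios), config$clamp))
  structure(
    list(
      probes = pr,
      diagnostics = list(max_inc = max_inc, iters = iters,
                         converged = converged, negative_nodes = neg_nodes),
      final = list(zeta = state$zeta, xi = state$xi, C = qn * state$xi,
                   t = state$t),
      mesh = mesh, model = kinetics$name, config = config,
      epsilon = epsilon, f = f, phi0 = phi0, probe_nodes = pidx
    ),
    class = "pnp_trajectory"
  )
}

state_fields <- function(state, species, config) {
  m <- length(state$zeta)
  ratios <- species$m / species$d
  qn <- exp(-clamp_exp(outer(state$zeta, ratios), config$clamp))
  C <- qn * state$xi
  fields <- lapply(seq_len(ncol(C)), function(i) C[, i])
  names(fields) <- species$name
  fields$phi <- state$zeta * config$V_T   # stored in mV
  fields
}

#' @export
print.pnp_trajectory <- function(x, ...) {
  cat(sprintf("pnp trajectory: model '%s', %d steps, dt = %g s, T = %g s\n",
              x$model, nrow(x$diagnostics$max_inc), x$config$dt, x$config$T))
  cat(sprintf("  Picard iterations per step: %.2f mean, %d max; %d step(s) unconverged\n",
              mean(x$diagnostics$iters), max(x$diagnostics$iters),
              sum(!x$diagnostics$converged)))
  cat(sprintf("  negative-concentration nodes flagged: %d\n",
              sum(x$diagnostics$negative_nodes)))
  cat("  final probe row:\n")
  print(utils::tail(x$probes, 1L), row.names = FALSE)
  invisible(x)
}

#' Write probe series to CSV
#'
#' Full double precision (17 significant digits), so repeated runs of the
#' same configuration are bit-identical on disk.
#'
#' @param traj a `pnp_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_probes_csv <- function(traj, path) {
  df <- traj$probes
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
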