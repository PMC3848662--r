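# Reaction kinetics: species tables, rate functions for the three enzyme
# systems, their Picard linearisation patterns, and derived kinetic
# quantities.
#
# Concentrations are muM throughout; second-order rate constants are
# muM^-1 s^-1. Quantities printed in molar units are converted on entry
# (1 M = 1e6 muM) to avoid silent 1e6 errors.
#
# A kinetics model carries, besides its species and rate function, the
# linearisation pattern used by the implicit-Euler/Picard stepper. For the
# mass-action models the pattern is encoded by term lists: each reaction
# term is a coefficient and per-species exponents, and within a Gauss-Seidel
# sweep a term's own-species factor is taken at the current iterate (k+1,
# moved to the system matrix when the term is dissipative), factors of
# already-updated species at k+1, and factors of not-yet-updated species at
# the previous iterate k -- exactly the superscript pattern of the
# per-model resolution algorithms.

#' Define an ionic species
#'
#' @param name species label.
#' @param d diffusion coefficient (simulation area/time, positive).
#' @param z integer valence.
#' @param C0 initial concentration (muM, nonnegative).
#' @param m mobility; defaults to `z * d` (Einstein relation in
#'   thermal-voltage units, so that `m/d = z`).
#' @return one-row data frame with columns `name, d, m, z, C0`.
#' @export
species_spec <- function(name, d, z, C0, m = z * d) {
  if (d <= 0) stop("diffusion coefficient must be positive for ", name)
  if (C0 < 0) stop("initial concentration must be nonnegative for ", name)
  data.frame(name = name, d = d, m = m, z = z, C0 = C0,
             stringsAsFactors = FALSE)
}

species_table <- function(names, d, z, C0, m = z * d) {
  do.call(rbind, Map(species_spec, names, d, z, C0, m))
}

# ---- rate functions ---------------------------------------------------------

as_conc_matrix <- function(c, ns) {
  if (is.matrix(c)) c else matrix(c, nrow = 1L, ncol = ns)
}

check_conc_domain <- function(C) {
  if (any(C < -1e-8)) {
    warning("negative concentrations passed to a rate function")
  }
}

#' Michaelis-Menten reduced rate
#'
#' The quasi-steady-state reaction velocity
#' `v = k2 * C10 * c2 / (c2 + kM)` of the basic enzyme reaction: the
#' substrate loses `v`, the product gains `v`, the free enzyme is untouched.
#'
#' @param c2 substrate concentration(s), muM.
#' @param params list with `k2` (1/s), `kM` (muM) and `C10` (total enzyme,
#'   muM).
#' @return rate(s), muM/s.
#' @examples
#' mm_reduced_rate(90, list(k2 = 1.4e4, kM = 90, C10 = 1)) # half-saturation
#' @export
mm_reduced_rate <- function(c2, params) {
  params$k2 * params$C10 * c2 / (c2 + params$kM)
}

# Evaluate mass-action term lists: rates(C)[, i] = sum_t coef_t prod_j C_j^pw
rates_from_terms <- function(C, terms) {
  ns <- length(terms)
  out <- matrix(0, nrow(C), ns)
  for (i in seq_len(ns)) {
    for (tm in terms[[i]]) {
      v <- rep(tm$coef, nrow(C))
      pw <- tm$powers
      for (j in which(pw > 0L)) v <- v * C[, j]^pw[j]
      out[, i] <- out[, i] + v
    }
  }
  out
}

#' Suicide-substrate mass-action rates
#'
#' Right-hand sides of the mechanism-based (suicide) inhibition scheme
#' `E + S <=> X -> Y`, `Y -> E + P`, `Y -> Ei`, for the concentration
#' ordering `(E, S, X, Y, Ei, P)`.
#'
#' @param c concentration vector of length 6 or a points-by-6 matrix (muM).
#' @param params list with rate constants `k1, km1, k2, k3, k4`.
#' @return rates in the shape of `c` (muM/s).
#' @export
suicide_rates <- function(c, params) {
  C <- as_conc_matrix(c, 6L)
  check_conc_domain(C)
  out <- rates_from_terms(C, suicide_terms(params))
  if (is.matrix(c)) out else drop(out)
}

suicide_terms <- function(p) {
  pw <- function(...) {
    v <- integer(6L); idx <- c(...); for (i in idx) v[i] <- v[i] + 1L; v
  }
  list(
    list(list(coef = -p$k1, powers = pw(1, 2)),
         list(coef = p$km1, powers = pw(3)),
         list(coef = p$k3, powers = pw(4))),
    list(list(coef = -p$k1, powers = pw(1, 2)),
         list(coef = p$km1, powers = pw(3))),
    list(list(coef = p$k1, powers = pw(1, 2)),
         list(coef = -(p$km1 + p$k2), powers = pw(3))),
    list(list(coef = p$k2, powers = pw(3)),
         list(coef = -(p$k3 + p$k4), powers = pw(4))),
    list(list(coef = p$k4, powers = pw(4))),
    list(list(coef = p$k3, powers = pw(4)))
  )
}

#' Cooperative two-site binding rates
#'
#' Right-hand sides of the two-site cooperative scheme
#' `S + E <=> X -> E + P`, `S + X <=> Y -> X + P`, for the concentration
#' ordering `(E, S, X, Y, P)`.
#'
#' @param c concentration vector of length 5 or a points-by-5 matrix (muM).
#' @param params list with rate constants `k1, km1, k2, k3, km3, k4`.
#' @return rates in the shape of `c` (muM/s).
#' @export
cooperative_rates <- function(c, params) {
  C <- as_conc_matrix(c, 5L)
  check_conc_domain(C)
  out <- rates_from_terms(C, cooperative_terms(params))
  if (is.matrix(c)) out else drop(out)
}

cooperative_terms <- function(p) {
  pw <- function(...) {
    v <- integer(5L); idx <- c(...); for (i in idx) v[i] <- v[i] + 1L; v
  }
  list(
    list(list(coef = -p$k1, powers = pw(1, 2)),
         list(coef = p$km1 + p$k2, powers = pw(3))),
    list(list(coef = -p$k1, powers = pw(1, 2)),
         list(coef = p$km1, powers = pw(3)),
         list(coef = -p$k3, powers = pw(2, 3)),
         list(coef = p$km3, powers = pw(4))),
    list(list(coef = p$k1, powers = pw(1, 2)),
         list(coef = -(p$km1 + p$k2), powers = pw(3)),
         list(coef = -p$k3, powers = pw(2, 3)),
         list(coef = p$km3 + p$k4, powers = pw(4))),
    list(list(coef = p$k3, powers = pw(2, 3)),
         list(coef = -(p$km3 + p$k4), powers = pw(4))),
    list(list(coef = p$k2, powers = pw(3)),
         list(coef = p$k4, powers = pw(4)))
  )
}

# ---- derived kinetic quantities --------------------------------------------

#' Suicide-substrate partition metrics
#'
#' The partition ratio `r = k3/k4` (product-forming vs inactivating turnover
#' of the committed intermediate), `mu = e0/s0`, and the determining factor
#' `(1 + r) * mu`: when it exceeds 1 the substrate is exhausted before the
#' enzyme is fully inactivated, below 1 all enzyme is inactivated, at 1 both
#' occur.
#'
#' @param k3,k4 branch rate constants (1/s), `k4 > 0`.
#' @param e0,s0 initial enzyme and substrate concentrations (muM), `s0 > 0`.
#' @return list with `r`, `mu`, `determining_factor` and a classification
#'   `label` in `c("exhausted", "enzyme-inactivated", "both")`.
#' @examples
#' partition_metrics(10, 2, 0.5, 0.5)$determining_factor # 6
#' @export
partition_metrics <- function(k3, k4, e0, s0) {
  if (k4 <= 0) stop("`k4` must be positive")
  if (s0 <= 0) stop("`s0` must be positive")
  r <- k3 / k4
  mu <- e0 / s0
  fac <- (1 + r) * mu
  label <- if (abs(fac - 1) < 1e-12) {
    "both"
  } else if (fac > 1) {
    "exhausted"
  } else {
    "enzyme-inactivated"
  }
  list(r = r, mu = mu, determining_factor = fac, label = label)
}

#' Derived kinetic constants
#'
#' Computes the Michaelis constant `kM = (km1 + k2)/k1` from elementary
#' constants, and for the two-site cooperative scheme the per-step
#' pseudo-equilibrium constants `K1 = (km1 + k2)/k1` and
#' `K2 = (k4 + km3)/k3` (whichever the supplied constants allow).
#'
#' @param params list of elementary rate constants; recognised names are
#'   `k1, km1, k2` (first binding step) and `k3, km3, k4` (second step).
#' @return list with `kM`/`K1` and, when `k3, km3, k4` are present, `K2`.
#' @export
derived_constants <- function(params) {
  out <- list()
  if (!is.null(params$k1)) {
    if (params$k1 <= 0) stop("`k1` must be positive")
    out$kM <- (params$km1 + params$k2) / params$k1
    out$K1 <- out$kM
  }
  if (!is.null(params$k3) && !is.null(params$km3)) {
    if (params$k3 <= 0) stop("`k3` must be positive")
    out$K2 <- (params$k4 + params$km3) / params$k3
  }
  out
}

#' Elementary constants from pseudo-equilibrium constants
#'
#' Inverse of [derived_constants()] for the cooperative scheme: given target
#' `K1`, `K2` and fixed `km1, k2, km3, k4`, returns the binding constants
#' `k1 = (km1 + k2)/K1` and `k3 = (k4 + km3)/K2`.
#'
#' @param K1,K2 target pseudo-equilibrium constants (positive).
#' @param km1,k2,km3,k4 fixed unbinding/turnover constants (1/s).
#' @return list with `k1` and `k3`.
#' @export
rate_constants_from_K <- function(K1, K2, km1 = 1, k2 = 1, km3 = 1, k4 = 1) {
  if (K1 <= 0 || K2 <= 0) stop("`K1` and `K2` must be positive")
  list(k1 = (km1 + k2) / K1, k3 = (k4 + km3) / K2)
}

# ---- presets ----------------------------------------------------------------

new_kinetics <- function(name, species, params, rate, scheme, terms = NULL,
                         product = NULL, substrate = NULL) {
  structure(
    list(name = name, species = species, params = params, rate = rate,
         scheme = scheme, terms = terms, product = product,
         substrate = substrate),
    class = "pnp_kinetics"
  )
}

#' @export
print.pnp_kinetics <- function(x, ...) {
  cat(sprintf("kinetics preset '%s' (%d species, %s linearisation)\n",
              x$name, nrow(x$species),
              if (x$scheme == "basic") "lagged-denominator" else "sweep"))
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Species table of the basic enzyme reaction
#'
#' Free enzyme, substrate and product with the reference diffusion
#' coefficients and valences (`d = 1e-3, 2e-3, 5e-3`; `z = 1, 0, 1`) and
#' initial concentrations `C10`, `C20`, 0 muM.
#'
#' @param C10,C20 initial enzyme and substrate concentrations (muM).
#' @param z valences, length 3.
#' @return species data frame.
#' @export
basic_species <- function(C10 = 1, C20 = 800, z = c(1, 0, 1)) {
  species_table(c("E", "S", "P"), d = c(1e-3, 2e-3, 5e-3), z = z,
                C0 = c(C10, C20, 0))
}

#' Basic (Michaelis-Menten) enzyme reaction preset
#'
#' Quasi-steady-state reduced kinetics: the substrate is consumed and the
#' product produced at rate `k2 * C10 * S/(S + kM)`; the free enzyme carries
#' no reaction term. In the stepper the free enzyme and product are solved
#' directly and only the substrate is Picard-iterated, its own factor at the
#' current iterate over a denominator lagged at the previous iterate.
#'
#' @param k2 catalytic rate constant (1/s).
#' @param kM Michaelis constant (muM; use `kM_M * 1e6` to enter molar
#'   values).
#' @param C10 total enzyme concentration entering the reduced rate (muM).
#' @param species species table, defaulting to [basic_species()].
#' @return a `pnp_kinetics` object.
#' @export
kinetics_basic <- function(k2 = 1.4e4, kM = 90, C10 = 1,
                           species = basic_species(C10 = C10)) {
  params <- list(k2 = k2, kM = kM, C10 = C10)
  rate <- function(C) {
    C <- as_conc_matrix(C, 3L)
    v <- mm_reduced_rate(C[, 2L], params)
    cbind(0, -v, v, deparse.level = 0)
  }
  new_kinetics("basic", species, params, rate, scheme = "basic",
               product = 3L, substrate = 2L)
}

#' Species table of the suicide-substrate system
#'
#' Enzyme, substrate, intermediates X and Y, inactivated enzyme and product
#' with the reference diffusion coefficients
#' (`1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6`) and valences `(1,0,1,1,1,0)`.
#'
#' @param e0,s0 initial enzyme and substrate concentrations (muM).
#' @return species data frame.
#' @export
suicide_species <- function(e0 = 0.5, s0 = 0.5) {
  species_table(c("E", "S", "X", "Y", "Ei", "P"),
                d = c(1e-3, 2e-3, 5e-3, 1e-3, 2e-3, 4e-6),
                z = c(1, 0, 1, 1, 1, 0),
                C0 = c(e0, s0, 0, 0, 0, 0))
}

#' Suicide-substrate kinetics preset
#'
#' Full mass-action kinetics of the mechanism-based inhibition scheme with
#' the reference rate constants `k1 = 2, km1 = 4, k2 = 12, k3 = 10, k4 = 2`.
#' All six species are swept in order inside one Picard loop; dissipative
#' own-species factors are implicit, bilinear partners take already-updated
#' values.
#'
#' @param k1 binding constant (muM^-1 s^-1); `km1, k2, k3, k4` in 1/s.
#' @param km1,k2,k3,k4 remaining rate constants.
#' @param e0,s0 initial enzyme/substrate concentrations (muM).
#' @param species species table, defaulting to [suicide_species()].
#' @return a `pnp_kinetics` object.
#' @export
kinetics_suicide <- function(k1 = 2, km1 = 4, k2 = 12, k3 = 10, k4 = 2,
                             e0 = 0.5, s0 = 0.5,
                             species = suicide_species(e0, s0)) {
  params <- list(k1 = k1, km1 = km1, k2 = k2, k3 = k3, k4 = k4,
                 e0 = e0, s0 = s0)
  rate <- function(C) {
    C <- as_conc_matrix(C, 6L)
    rates_from_terms(C, suicide_terms(params))
  }
  new_kinetics("suicide", species, params, rate, scheme = "sweep",
               terms = suicide_terms(params), product = 6L, substrate = 2L)
}

#' Species table of the cooperative system
#'
#' Enzyme, substrate, single- and dual-bound complexes and product, sharing
#' the diffusion coefficients of the first five suicide-substrate species;
#' valences `(1,0,1,1,0)` by analogy (charged enzyme forms, neutral
#' substrate and product).
#'
#' @param e0,s0 initial enzyme and substrate concentrations (muM).
#' @return species data frame.
#' @export
cooperative_species <- function(e0 = 0.5, s0 = 0.5) {
  species_table(c("E", "S", "X", "Y", "P"),
                d = c(1e-3, 2e-3, 5e-3, 1e-3, 2e-3),
                z = c(1, 0, 1, 1, 0),
                C0 = c(e0, s0, 0, 0, 0))
}

#' Cooperative two-site kinetics preset
#'
#' Mass-action kinetics of the two-site binding scheme, parameterised by the
#' pseudo-equilibrium constants `K1` and `K2` (only these are reported for
#' the reference runs): the unbinding/turnover constants are fixed at
#' `km1 = k2 = km3 = k4 = 1` 1/s and the binding constants derived as
#' `k1 = (km1 + k2)/K1`, `k3 = (k4 + km3)/K2`. Positive cooperativity
#' corresponds to `K1 = 1000, K2 = 0.001`; negative to `K1 = 0.5, K2 = 100`.
#'
#' @param K1,K2 pseudo-equilibrium constants.
#' @param km1,k2,km3,k4 fixed constants (1/s).
#' @param e0,s0 initial enzyme/substrate concentrations (muM).
#' @param species species table, defaulting to [cooperative_species()].
#' @return a `pnp_kinetics` object.
#' @export
kinetics_cooperative <- function(K1 = 1000, K2 = 0.001,
                                 km1 = 1, k2 = 1, km3 = 1, k4 = 1,
                                 e0 = 0.5, s0 = 0.5,
                                 species = cooperative_species(e0, s0)) {
  kk <- rate_constants_from_K(K1, K2, km1, k2, km3, k4)
  params <- list(k1 = kk$k1, km1 = km1, k2 = k2, k3 = kk$k3, km3 = km3,
                 k4 = k4, e0 = e0, s0 = s0, K1 = K1, K2 = K2)
  rate <- function(C) {
    C <- as_conc_matrix(C, 5L)
    rates_from_terms(C, cooperative_terms(params))
  }
  new_kinetics("cooperative", species, params, rate, scheme = "sweep",
               terms = cooperative_terms(params), product = 5L,
               substrate = 2L)
}

#' Custom mass-action kinetics
#'
#' Builds a kinetics model from explicit mass-action term lists: for each
#' species a list of terms, each a `list(coef =, powers =)` with `powers`
#' an integer vector of per-species exponents. The Picard pattern follows
#' the preset convention (dissipative own-species factors implicit, partner
#' factors Gauss-Seidel).
#'
#' @param species species data frame (see [species_spec()]).
#' @param terms per-species term lists.
#' @param name model label.
#' @param product index of the species treated as "product" by the study
#'   harnesses.
#' @return a `pnp_kinetics` object.
#' @export
kinetics_custom <- function(species, terms, name = "custom",
                            product = nrow(species)) {
  ns <- nrow(species)
  if (length(terms) != ns) stop("`terms` must have one entry per species")
  for (i in seq_len(ns)) {
    for (tm in terms[[i]]) {
      if (length(tm$powers) != ns) {
        stop("every term's `powers` must have length ", ns)
      }
    }
  }
  rate <- function(C) rates_from_terms(as_conc_matrix(C, ns), terms)
  new_kinetics(name, species, list(), rate, scheme = "sweep", terms = terms,
               product = product)
}

#' Look up a kinetics preset by name
#'
#' @param name one of `"basic"`, `"suicide"`, `"cooperative"`.
#' @param ... passed to the preset constructor.
#' @return a `pnp_kinetics` object.
#' @export
kinetics_preset <- function(name = c("basic", "suicide", "cooperative"), ...) {
  name <- match.arg(name)
  switch(name,
         basic = kinetics_basic(...),
         suicide = kinetics_suicide(...),
         cooperative = kinetics_cooperative(...))
}
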