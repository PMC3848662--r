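---
title: "Methods: finite-element electrodiffusion with enzyme kinetics"
author: "pnpfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite-element electrodiffusion with enzyme kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpfem)
```

## The model

`pnpfem` simulates the electromigration of reacting ions through a
two-dimensional cell: each species concentration $C_i(t,x)$ obeys a
Nernst–Planck equation whose flux combines Fickian diffusion and electrical
drift,

$$\partial_t C_i - d_i \Delta C_i - m_i\,\mathrm{div}(C_i \nabla\phi) =
F_i(C_1,\dots,C_{N_s}),$$

while the electric potential $\phi$ is determined self-consistently by the
Poisson equation $-\varepsilon\Delta\phi = \sum_i z_i C_i - f$, with $f$ a
fixed-charge density. On the membrane $\partial\Omega$ the species fluxes
vanish (no-flux Robin condition $d_i \partial_\nu C_i + m_i C_i
\partial_\nu\phi = 0$) and the potential is grounded ($\phi = 0$). The cell
is an ellipse with semi-axes $a, b$. No constant-field (Goldman) or
electroneutrality simplification is made: the potential is resolved in
space and time together with the concentrations.

Three reaction presets cover the classic enzyme systems:

* **basic** — the Michaelis–Menten reduction of $S + E \rightleftharpoons
  SE \to P + E$. After the quasi-steady-state elimination of the complex,
  the substrate is consumed (and product produced) at rate
  $k_2 C_{1,0} S/(S + k_M)$ with $k_M = (k_{-1}+k_2)/k_1$; the free enzyme
  carries no reaction term, so its concentration should remain constant —
  a sharp correctness check the acceptance suite exercises.
* **suicide** — the mechanism-based inhibition scheme
  $E+S \rightleftharpoons X \to Y$, $Y \to E+P$ (rate $k_3$),
  $Y \to E_i$ (rate $k_4$), in full mass action over six species. The
  partition ratio $r = k_3/k_4$ and $\mu = e_0/s_0$ give the determining
  factor $(1+r)\mu$: above 1 the substrate exhausts, below 1 the enzyme is
  fully inactivated (`partition_metrics()`).
* **cooperative** — two-site binding
  $S+E \rightleftharpoons X \to E+P$, $S+X \rightleftharpoons Y \to X+P$,
  parameterised by the pseudo-equilibrium constants
  $K_1 = (k_{-1}+k_2)/k_1$, $K_2 = (k_4+k_{-3})/k_3$; positive
  cooperativity ($K_1 = 1000$, $K_2 = 10^{-3}$) produces the sigmoidal
  product curve.

Arbitrary mass-action networks can be supplied through
`kinetics_custom()` as term lists (coefficient + per-species exponents).

## Discretisation

**Slotboom change of variables.** Each drift-diffusion operator is
symmetrised by substituting $Z_i = C_i\,p_i$ with $p_i =
\exp((m_i/d_i)\phi)$, $q_i = 1/p_i$. The transformed equation is a
weighted diffusion equation, and its P1 Galerkin matrices — mass
$A_{ij} = \int q_i \Phi_j \Phi_i$ and stiffness $R_{ij} = d_i \int q_i
\nabla\Phi_j\cdot\nabla\Phi_i$ — are symmetric positive (semi)definite, so
every linear solve is a sparse Cholesky solve.

**P1 elements.** The mesh is a conforming triangulation with one degree of
freedom per node; membrane nodes (edges owned by a single triangle) form
the Dirichlet set for the potential. Weighted integrals are evaluated by
interpolating the nodal potential to quadrature points before
exponentiation; the default rule is the degree-2 edge-midpoint rule (exact
for products of P1 functions), with a 6-point degree-4 rule available for
the exponential weights (`solver_config(degree = 4)`). The exponent is
clamped at ±50 with a counter (`clamp_count()`); the reference runs stay
orders of magnitude below the clamp.

**Time stepping.** Implicit Euler. One step performs, in order: (1) the
Poisson solve for $\phi^{n+1}$ from the lagged charge density
$\sum_i z_i q_i^n Z_i^n - f$ (no inner Gummel coupling iteration); (2) the
factor update $q_i^{n+1} = \exp(-(m_i/d_i)\phi^{n+1})$; (3) the species
solves $(A^{n+1} + \Delta t\,R^{n+1})\,\xi^{n+1} = A^n \xi^n + \Delta t\,
S^{n+1}$.

**Picard linearisation.** Reaction terms are handled per model. For the
basic preset only the substrate equation is nonlinear: its own factor is
taken at the current iterate while the Michaelis denominator is lagged
($k_M + q_2 Z_2^{(k)}$), so each iterate adds a positive weighted mass
matrix to the system; the enzyme is solved directly before, the product
directly after with the converged substrate. For the mass-action presets
all species are swept in order inside one Picard loop (Gauss–Seidel):
a term's own-species factor is implicit when dissipative (moved to the
matrix), partner factors of already-updated species enter at the current
iterate and later species at the previous one. The loop stops when the
summed $L^2$ increment drops below `eps` ($10^{-4}$ by default, the value
used for all three reference runs; the cap is `max_picard = 50`, and
non-convergence is flagged with a warning or abort per configuration).
Picard iterates are initialised at the previous time level.

This construction makes every system matrix symmetric positive definite,
and yields a discrete conservation identity: for a reaction-free species,
$\mathbf{1}^\top A^{n+1}\xi^{n+1} = \mathbf{1}^\top A^n\xi^n$ exactly,
because the weighted-stiffness columns sum to zero. The test suite checks
this to $10^{-10}$ relative per step.

## Units and the electrostatic coupling

Concentrations are µM throughout; molar inputs are converted on load
(`kM: {value: 9.0e-5, unit: M}` becomes 90 µM, M⁻¹s⁻¹ binding constants
become µM⁻¹s⁻¹). Potentials are carried internally in thermal-voltage
units ($V_T = 25.693$ mV), so Boltzmann exponents are dimensionless; the
initial membrane potential $\phi_0 = -80$ mV corresponds to $-3.11$
internal units, applied on interior nodes with the membrane grounded.

Mobilities are rarely tabulated for such models; by default the Einstein
relation in thermal-voltage units is used, $m_i = z_i d_i$ (so $m_i/d_i =
z_i$), overridable per species.

The permittivity $\varepsilon$ (a Debye-ratio-like parameter here) must be
chosen, and it controls how strongly µM-scale charge imbalances feed back
into drift. The package defaults to $\varepsilon = 10^6$ in µM units —
equivalently, the Poisson source is measured in molar units — which puts
the self-consistent potential in the sub-mV range for the reference runs.
This weak-coupling regime is the one consistent with the reported
behaviour of all three reference systems (a constant free-enzyme profile,
kinetics matching well-mixed ODE solutions): with $\varepsilon = O(1)$ in
µM units, the ~800 µM of charged product accumulated by the basic run
would produce potentials of hundreds of thermal units and visibly deplete
every charged species within 0.2 s, which is not what those systems do.
$\varepsilon$ remains fully configurable, and the coupling-sensitive unit
tests run at $\varepsilon = O(1)$ where the potential feedback is strong.

The fixed-charge density is $f = 0.1$ (µM charge units) by default; its
physical unit is ambiguous in the sources this model family comes from,
so it is treated as a constant source density in simulation units.

Cooperative runs pose one more identifiability problem: only $K_1$ and
$K_2$ are reported for the reference parameterisation. The preset fixes
$k_{-1} = k_2 = k_{-3} = k_4 = 1\,\mathrm{s}^{-1}$ and derives $k_1, k_3$
from $K_1, K_2$ (`rate_constants_from_K()`); this choice is an assumption,
not a reported fact. The cooperative valences are likewise unreported and
are set by analogy with the suicide system (charged enzyme forms, neutral
substrate and product): $z = (1, 0, 1, 1, 0)$.

## Mesh generation

The triangulator is deterministic: nodes are placed on nested scaled
ellipses, ring $j$ of $n$ carrying $6j$ nodes equally spaced in arc length
(perimeters of nested similar ellipses scale linearly, so the spacing is
uniform and rings align); consecutive rings are stitched by a merge sweep
into counter-clockwise bands, and the centre is a 6-spoke fan. The
six-fold centre is deliberate: among uniform $k$-fans, $k = 6$ is the only
one whose P1 Laplace stencil is exact for quadratics
($k\tan(\pi/k)/4 = k\sin(2\pi/k)/6$ only at $k=6$), which preserves the
scheme's second-order spatial accuracy at the centre — exactly where the
reference probes sit. Membrane nodes lie on the ellipse to machine
precision, the mesh size satisfies $h \le 1.25\,h_{\mathrm{target}}$, and
the triangles are near-equilateral except for mild stretching along the
major axis. External meshes can be supplied in Gmsh MSH 2.2 ASCII or a
plain node/element text format.

## Study harnesses and problem sizes

`convergence_study()` reruns a model on $h \in \{0.3, 0.1, 0.05\}$ with
the time step tied to the mesh, $\Delta t = h\,T/16$, from constant
initial conditions, and records the error functional

$$E_h = \Delta t \sum_i \sum_n \max_k \left\Vert Z_i^{n,k+1} -
Z_i^{n,k}\right\Vert_{L^2(\Omega)},$$

the time-step-weighted sum of the largest Picard increments. $E_h$ is a
self-consistency measure (zero for a linear problem resolved in one
iterate) and must fall strictly under simultaneous mesh/time refinement;
that monotone decrease — not any particular printed value — is the
property the acceptance suite asserts, because $E_h$'s absolute scale
depends on unreported details (mesh generator, quadrature, study horizon).
The study horizons used are $T = 0.2$ s for the basic model (its full
reference duration) and $T = 1$ s for the suicide and cooperative models,
long enough to traverse the fast complex-formation transient and a
substantial part of the substrate decay. Because the time step is tied to
the mesh, each run takes $16/h$ steps regardless of $T$.

`stability_study()` reruns one model at $\Delta t$, $\Delta t/2$,
$\Delta t/4$ to a common final time on one mesh ($h = 0.25$ by default)
and reports pairwise relative $L^2$ discrepancies of the final product
field; for an unconditionally stable first-order scheme these are small
and shrink ~2× per halving, and the reference ladders
($10^{-3}, 5\cdot10^{-4}, 2.5\cdot10^{-4}$ s at $T = 0.5$ s for basic;
$10^{-2}, 5\cdot10^{-3}, 2.5\cdot10^{-3}$ s at $T = 4$ s for the other
two) come out well below the 2% band asserted by the tests.

`poisson_order_study()` isolates the spatial discretisation with a
manufactured solution: on the unit disk with unit net charge the potential
is $\phi = (1-r^2)/4$; the observed $L^2$ order over
$h \in \{0.2, 0.1, 0.05\}$ lands in $[1.8, 2.2]$.

## Numerical choices and degenerate inputs

* Linear systems are solved by sparse Cholesky; a symbolic factorisation
  is computed once per mesh (all operators share the adjacency pattern)
  and refactorised numerically per solve. The Poisson interior block is
  factorised once per run.
* Dirichlet rows are eliminated (reduced interior system), not penalised.
* A final time that is not a multiple of $\Delta t$ runs
  $\lceil T/\Delta t\rceil$ steps; the stability harness instead rounds
  $\Delta t$ to the nearest divisor of $T$ with a note.
* Probes are the nearest node to the requested point, ties broken by
  lowest index; node 1 of a generated mesh is the cell centre.
* Reconstructed concentrations are monitored for negativity
  (threshold $-10^{-8}$ µM) and violations counted in the diagnostics;
  on the near-acute generated meshes the reference runs report none.
* Degenerate inputs fail loudly: non-positive geometry or rate
  denominators, non-conforming meshes (an edge in three triangles),
  meshes with no interior node (empty Poisson system), negative initial
  concentrations, non-finite reaction rates (reported with species and
  element index).

## What the synthetic setups do and do not show

All validation inputs are generated in code: meshes from the deterministic
generator, degenerate single-element cases, and the three reference
parameter sets. The tests therefore demonstrate internal correctness
(closed-form element matrices, high-order quadrature oracles, a
hand-written scalar backward-Euler/Picard oracle in the well-mixed limit,
independent ODE integration of the kinetics, conservation identities,
manufactured-solution convergence) — they do not validate the model
against laboratory membrane data, nor the parameter identification
questions noted above (ε, mobilities, cooperative rate constants, the
unit of $f$). Within the weak-coupling default the electric drift is a
small perturbation; runs with $\varepsilon = O(1)$ exercise strong
coupling but have no external reference to compare against.

## Known limitations

* One suicide-substrate claim is quantitatively out of reach of the
  printed parameters: with $k = (2, 4, 12, 10, 2)$ s⁻¹ and $e_0 = s_0 =
  0.5$ µM, the well-mixed kinetics leave 7.7% of the substrate at
  $t = 4$ s (both the FEM solution and an independent stiff ODE
  integration agree); the substrate falls below 1% of $s_0$ only near
  $t \approx 9.4$ s. The acceptance suite keeps the stricter 4-second
  check (and it fails there by design); the companion regression test
  asserts the verifiable substance — monotone exhaustion consistent with
  $(1+r)\mu = 6 > 1$, agreement with the ODE oracle, and sub-1% substrate
  by $t = 10$ s.
* P1 elements only; no mass lumping, no P2, no adaptive refinement, no
  curved boundary elements (the polygonal boundary costs $O(h^2)$,
  consistent with the overall order).
* Implicit Euler is first-order in time; Newton linearisation and
  operator splitting are out of scope, as are nonzero or time-dependent
  membrane potentials and stochastic kinetics.
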