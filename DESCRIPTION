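Package: pnpfem
Title: Finite-Element Simulation of Ion Electromigration Through Biological Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Solves coupled Nernst-Planck/Poisson (electrodiffusion) systems on
    two-dimensional cell-shaped domains with enzymatic reaction kinetics. The
    drift-diffusion operators are symmetrised by the Slotboom change of
    variables and discretised with P1 triangular finite elements; time stepping
    is implicit Euler with per-model Picard fixed-point iteration and
    Gauss-Seidel species sweeps. Ships reaction presets for the basic
    (Michaelis-Menten) enzyme reaction, the suicide-substrate system and
    cooperative two-site binding, plus mesh-convergence and time-step-stability
    study harnesses, a deterministic ellipse mesh generator, Gmsh/VTK/CSV
    input-output and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
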