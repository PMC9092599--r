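Package: vasoseed
Title: Lagrangian Cell Transport and Deposition in Perfused Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order simulator of endothelial-cell seeding in perfused
    vascular networks. Steady flow is solved on a graph of cylindrical vessel
    segments with Hagen-Poiseuille conductances and Darcy leakage through
    porous walls to a constant-pressure parenchyma; cells are tracked as
    Lagrangian point particles under drag, buoyancy and gravity; wall impacts
    are resolved with one of three stochastic deposition rules (deposit on
    contact, a receptor-ligand adhesion probability, or a Stokes-number
    inertial-impaction probability). Seeding efficiency, per-facet deposition
    maps and the coefficient-of-variation uniformity statistic are reported as
    functions of injection flow rate, together with synthetic bifurcating-tree
    generation, a plain-text network format, VTK centerline export and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
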