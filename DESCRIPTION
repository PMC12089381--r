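Package: phosdyn
Title: Hybrid Molecular Dynamics/Monte Carlo Simulation of Enzymatic
    Phosphorylation of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained, implicit-solvent simulation of kinase-driven
    serine phosphorylation of intrinsically disordered proteins and their
    condensates. Combines one-bead-per-residue Langevin dynamics (HPS-family
    force field with Ashbaugh-Hatch, screened-electrostatic and cation-pi
    pair potentials, rigid folded domains) with Metropolis Monte Carlo
    phosphorylation steps driven by an ATP/ADP chemical potential
    difference, plus a detailed-balance reservoir-exchange step that closes
    the phosphorylation cycle. Markov state model machinery certifies the
    thermodynamic consistency of the driven dynamics (dissipated heat per
    cycle from local detailed balance, implied timescales,
    Chapman-Kolmogorov tests, block bootstrap errors). Kinetics estimators
    recover per-serine phosphorylation and contact rates, survival-curve
    fits and phosphorylation-order statistics, and density-based clustering
    under periodic boundaries quantifies condensate dissolution upon
    hyperphosphorylation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
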