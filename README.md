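# phosdyn

Coarse-grained simulation of enzymatic phosphorylation of disordered
proteins — and a Markov-state-model certificate that the chemically
driven dynamics is thermodynamically consistent.

Kinases such as casein kinase 1 delta (CK1δ) phosphorylate serines of
disordered substrates like the TDP-43 low-complexity domain (LCD,
residues 261–414), consuming ATP and holding the system in a
non-equilibrium steady state. `phosdyn` is for simulators who want to
study such chemistry-coupled dynamics at one bead per residue:

* **Engine** — implicit-solvent Langevin dynamics (BAOAB splitting,
  rigid folded domains via quaternions) with an HPS-family force field:
  Ashbaugh–Hatch hydropathy-scaled Lennard-Jones, Debye-screened
  electrostatics, optional cation–π enhancement, harmonic bonds,
  periodic boundaries. Every `mc_interval` steps a Metropolis step may
  phosphorylate (or dephosphorylate) the serine in contact with the
  enzyme active site,

      A(Ser→pSer) = min(1, exp(−β ΔU_P − β Δμ_P)),

  where Δμ_P is the ADP−ATP chemical potential difference (physiological
  preset −48 kJ/mol), and a detailed-balance reservoir-exchange step far
  from the enzyme closes the reaction cycle.
* **MSM validation** — the trajectory is discretized onto the four-state
  cycle (1 unbound·Ser, 2 bound·Ser, 3 bound·pSer, 4 unbound·pSer); from
  non-reversible maximum-likelihood transition matrices and first-order
  rates `k_ij = T_ij(τ)/τ`, local detailed balance gives the dissipated
  heat per cycle

      Δμ_cycle = −RT ln( k12 k23 k34 k41 / (k14 k43 k32 k21) ),

  which must equal the applied Δμ_P. Implied timescales,
  Chapman–Kolmogorov tests and circular block-bootstrap errors qualify
  the model.
* **Kinetics** — per-serine phosphorylation rates from censored
  first-passage times (`r_P = (n+1)/Θ` with a uniform prior), inverse
  cumulative survival curves with single-exponential and
  binding-conditioned fits, phosphorylation-order matrices,
  arrival-order histograms, contact rates and their correlation.
* **Condensates** — DBSCAN clustering under periodic boundaries,
  condensate fraction and enzyme attachment, circular-mean centering,
  radial density profiles, pSer-per-chain distributions, per-residue
  energy decompositions, dissolution-onset detection.
* **Workbench** — bundled TDP-43 LCD (261–414) and CK1δ kinase-domain
  sequences with author numbering, engineered sequence variants
  (no-charge, averaged-interaction, equally spaced serines), synthetic
  generators with stored ground truth, TSV/JSON I/O, run manifests and a
  CLI (`inst/cli/phosdyn.R`).

## Worked example: certifying a driven simulation

The desk-scale validation system is a two-bead substrate (a sticky
anchor bonded to the single reactive serine) plus a compact rigid
four-bead enzyme whose Asp-Phe-Gly triangle is the annotated active
site.

```r
library(phosdyn)

sys <- build_toy_validation_system(box = 12)
cfg <- sim_config(n_steps = 8e7, box_side = 12, friction = 1,
                  reservoir_enabled = TRUE, reservoir_distance = 2.5,
                  reservoir_interval = 20, phospho_interval = 60,
                  dmu_p = -10, seed = 42)
tr  <- run_hybrid_simulation(sys$topology, sys$params, cfg,
                             positions = sys$positions,
                             feature_beads = c(1, 2))

dmol  <- pmin(tr$frames$features[, 1], tr$frames$features[, 2])
bound <- assign_two_states(dmol, cutoff = 1.8, soft_margin = 0.15)
dtraj <- build_cycle_trajectory(bound, tr$frames$chem[, 1], burn_in = 100)
est   <- estimate_dmu_cycle(dtraj, tau = 25, n_boot = 30, block_len = 250)
cat(sprintf("dmu_cycle = %.2f +/- %.2f kJ/mol\n", est$value, est$sem))
```

```
dmu_cycle = -9.81 +/- 0.89 kJ/mol
```

The estimated dissipation matches the applied driving of −10 kJ/mol
within its bootstrap error; the same protocol at Δμ_P = 0 gives
−0.14 ± 0.38 and at −5 gives −3.92 ± 0.55 kJ/mol (the intermediate
driving shows the ~1 kJ/mol residual coarse-graining bias discussed in
the methods vignette, still within two standard errors). Edge-resolved
ratios `RT ln(k_ij/k_ji)` show the chemical edge 2⇌3 shifting by the
applied difference while the reservoir edge stays exactly static. The
numbers above are what the example prints for seed 42; a run takes a
few minutes on one core.

Sequence bookkeeping example — the averaged-interaction variant of the
bundled LCD:

```r
lcd <- load_fixture("tdp43_lcd")
sequence_average_params(lcd, load_parameter_set("hps"))
#>      mass     sigma    lambda
#> 98.956800   0.54331   0.64039
```

## Notes

* Units: nm, ps, amu, kJ/mol. Seeds are explicit everywhere; fixed seeds
  reproduce event logs bit-exactly.
* Structures of folded domains (PDB 6RU7, AlphaFold P48730) are
  user-supplied inputs; the package never downloads.
* The methods vignette (`vignettes/phosdyn-methods.Rmd`) documents the
  models, estimators, toy-system design and known limitations.
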