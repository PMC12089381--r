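---
title: "Chemically driven coarse-grained simulation of enzymatic phosphorylation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosdyn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Kinases phosphorylate serine residues of disordered proteins while
consuming ATP, which holds the cell away from thermodynamic equilibrium.
For the TAR DNA-binding protein TDP-43, hyperphosphorylation of the
low-complexity domain (LCD, residues 261-414) by casein kinase 1 delta
changes its condensation behaviour, and residue-resolved simulations can
ask *which* serines are phosphorylated, *why*, and *what that does to a
condensate*.  `phosdyn` implements the full simulation-and-analysis stack
for that question at one bead per residue:

1. an implicit-solvent Langevin engine with rigid folded domains and an
   HPS-family force field (`params`, `engine`);
2. Metropolis Monte-Carlo chemistry — a phosphorylation step biased by the
   ATP/ADP chemical potential difference, and a detailed-balance
   reservoir-exchange step that closes the reaction cycle the way a
   phosphatase would;
3. Markov-state-model machinery that *certifies thermodynamic
   consistency*: the heat dissipated per completed phosphorylation cycle,
   estimated purely from transition-rate ratios, must equal the applied
   chemical potential difference (`msm`);
4. kinetics estimators for per-serine phosphorylation and contact rates,
   survival-curve fits and phosphorylation-order statistics (`kinetics`);
5. condensate identification by density-based clustering under periodic
   boundaries, with radial profiles, enzyme-attachment and per-residue
   energy decompositions (`condensate`).

# Force field

Each residue is one bead with mass, van der Waals diameter sigma,
hydropathy lambda in [0, 1] and integer charge; the packaged table
(`inst/extdata/hps_table.tsv`) is the Kapcha-Rossky-based HPS set with
four-significant-figure masses.  Non-bonded pairs interact through

* the **Ashbaugh-Hatch potential**: for `r <= 2^(1/6) sigma` it is the 12-6
  Lennard-Jones potential (well depth `eps_ah = 0.8368` kJ/mol) shifted up
  by `(1 - lambda) eps`; beyond the minimum the Lennard-Jones tail is
  multiplied by `lambda`.  Arithmetic-mean combination for sigma and
  lambda.  Cutoff 2 nm.
* the **Yukawa potential** `k_e q_i q_j exp(-r/lambda_D) / (eps_r r)` with
  Debye length 1 nm (about 100 mM implicit salt) and dielectric 80, cutoff
  3.5 nm.
* an optional **cation-pi well** between {Arg, Lys} and {Phe, Trp, Tyr}, a
  12-6 well of depth `cation_pi_epsilon` (default 3.138 kJ/mol) with the
  same sigma rule — this distinguishes the `modified_hps` variant from
  plain `hps`.

Bonds are harmonic, `U = k/2 (r - r0)^2` with `k = 8033` kJ/(mol nm^2) and
`r0 = 0.38` nm.  Pairs where at least one bead belongs to a rigid folded
group have the hydropathy-scaled part of the Ashbaugh-Hatch term and the
cation-pi well multiplied by `folded_scale = 0.7` (a 30% reduction,
implemented as `lambda -> 0.7 lambda`); electrostatics are not scaled.
All of these constants are fields of `load_parameter_set()` and can be
overridden.

**Phospho-serine defaults.** The pSer bead (code `"p"`) carries mass
167.05 amu (serine plus a phosphate group), sigma 0.636 nm, lambda 0.40
and charge -2.  These are package defaults in the spirit of the
phospho-residue extensions of the HPS family and are deliberately
overridable; any quantitative use against experiment should supply a
vetted phospho-residue parameterization.

**Sequence variants.**  `load_parameter_set("no_charge")` zeroes every
charge except pSer.  `build_sequence_variant()` produces the
averaged-interaction chain: every non-Ser bead is replaced by one bead
carrying the *whole-chain* averages of the TDP-43 LCD — 98.957 amu,
0.54331 nm, lambda 0.64039 with zero charge.  We verified numerically
that averaging over all 154 residues (not the 130 non-Ser residues)
reproduces these three printed constants to all shown digits, and the
package therefore averages over the whole chain.  The `equi_ser` variant
keeps the Ser count (24) and spaces the serines evenly, ties broken
toward the N terminus.

# Engine

Langevin dynamics at 300 K with time step 0.01 ps, friction 0.001 ps^-1
on each velocity component by default, integrated with a BAOAB splitting
(kick - drift - Ornstein-Uhlenbeck - drift - kick).  The splitting is
well behaved at very low friction, and with `friction -> 0` and `T = 0`
it reduces to velocity Verlet.  Rigid groups (the kinase folded domain;
optionally the LCD helix 320-332) move as rigid bodies: the total force
translates the centre of mass, the torque rotates a unit quaternion about
the body-frame principal axes, with a rotational drag of 4 ps^-1 per axis
and matching thermal noise per principal moment.  Rigidity is exact by
construction (member positions are always `centre + R(q) x_body`), which
the tests verify to below 1e-6 nm drift.  Collinear rigid groups are
rejected at setup because their inertia tensor is singular.

Coordinates are kept wrapped in the periodic box and all distances use
minimum-image convention.  The pair loop is a direct O(N^2) scan with an
early exit on the squared cutoff; at the package's validated scales
(up to a few hundred beads) this is not the bottleneck and a cell list
would add machinery without changing any result.  Energies are reported
split into Ashbaugh-Hatch, Yukawa, cation-pi and bond terms.

**Monte-Carlo chemistry.**  Every `mc_interval = 200` MD steps the engine
checks whether a phosphosite is in contact with the enzyme active site:
all three distances to the active-site beads (Asp149, Phe150, Gly151 of
the kinase, by author numbering) must be below 1 nm; if several sites
qualify, only the closest (smallest mean distance, ties to the lowest
residue index) is considered.  A Metropolis swap Ser -> pSer is accepted
with probability `min(1, exp(-beta dU_P - beta dmu_P))`, where `dU_P` is
the potential-energy difference of the configuration with pSer minus that
with Ser, computed over the pair interactions of the site bead (exactly
the full-system difference, verified to 1e-9 kJ/mol in the tests), and
`dmu_P` is the ADP-minus-ATP chemical potential difference.  The reverse
swap uses the sign-flipped exponent.  `dmu_P = -48` kJ/mol is the
physiological preset, stored as the constant `DMU_PHYSIOLOGICAL` exactly
as given rather than re-derived from concentrations.  With the reservoir
enabled (validation runs only), whenever all three distances exceed
`reservoir_distance` (half the box side by default) the substrate's
chemical identity may additionally be swapped with plain Metropolis
acceptance `min(1, exp(-beta dU))` — an equilibrium exchange with an
implicit reservoir of phosphorylated/unphosphorylated protein that closes
the cycle without injecting energy.

Both MC steps take an attempt-interval parameter (`phospho_interval`,
`reservoir_interval`, in units of MC checks; default 1 = the production
behaviour of attempting at every check).  Attempt frequency cancels from
every rate *ratio*, so these throttles do not touch the thermodynamics;
they exist because the Markov-state analysis needs each cycle edge to be
slower than the observation lag (next section).

# Thermodynamic consistency via a 4-state MSM

A driven simulation is only trustworthy if its steady state dissipates
exactly the free energy the chemistry supplies.  The package certifies
this on a cycle: states 1 = unbound/Ser, 2 = bound/Ser, 3 = bound/pSer,
4 = unbound/pSer.  From the discretized trajectory a non-reversible
maximum-likelihood transition matrix `T(tau)` is estimated by
sliding-window counts, first-order rates `k_ij = T_ij(tau)/tau` are
formed (the first-order formula is isolated in `transition_rates()` so a
matrix-logarithm alternative can be swapped in), and the local
detailed-balance relation gives the dissipated heat per forward cycle

```
dmu_cycle = -RT log( k12 k23 k34 k41 / (k14 k43 k32 k21) ).
```

This quantity depends only on rate ratios; uniform rescaling of all rates
(e.g. by attempt frequencies) leaves it unchanged.  For the undriven
edges (binding 1<->2 and 3<->4, reservoir 4<->1), `RT log(k_ij/k_ji)` is
a state free-energy difference independent of the driving; the chemical
edge 2<->3 shifts linearly with `dmu_P`.  Model quality is checked by
implied timescales `t_i = -tau / log |lambda_i|` (plateau over `tau`) and
the Chapman-Kolmogorov test `T(n tau) = T(tau)^n`, both with circular
block-bootstrap confidence intervals (blocks of `10 tau` frames by
default; the resampling unit is a package choice).

**Bound/unbound assignment.**  The default assigner thresholds the
contact-criterion distance with a soft band (linear ramp of half-width
`soft_margin` around the cutoff); a linear VAMP projection — the dominant
singular function of the whitened time-lagged feature correlation — with
a two-centre split is available as `method = "vamp_linear"`.  Either way,
frames whose soft probability falls in (0.30, 0.70) are relabeled by
transition-based state assignment: an uncertain stretch carries the
previous firm state to its midpoint and the following firm state after
it.  The assigner is a plain function argument, so a neural-network
backend could be dropped in without touching the downstream math, which
is deliberately independent of how states are found.

# The toy validation system

The desk-scale system used by the consistency tests
(`build_toy_validation_system()`) is a two-bead substrate — a sticky
neutral anchor (custom code `"u"`, lambda 1) bonded to the single
phosphosite Ser — plus a rigid four-bead enzyme: a compact Asp-Phe-Gly
triangle (edge 0.3 nm, the annotated active site) with a back bead
behind its centroid.  A lumped four-state model only reproduces the
microscopic dissipation when every lumped state is internally
equilibrated on the lag timescale; each design choice below removes one
slow internal mode that would otherwise leak dissipation out of the
observed cycle (projection always *under*-estimates entropy production,
so every such mode biases the recovered affinity toward zero):

* **binding energy is carried by the anchor alone.**  The toy overrides
  Ser and pSer to hydropathy 0.15, so the chemical identity barely
  couples to binding stability.  If the reactive bead contributed to
  binding, the chemistry would select between docked and dangling
  sub-states of the bound ensemble and the measured unbinding rate of
  bound-Ser would change with the driving — observed directly as a
  driven shift of the binding edge before this choice was made.  The toy
  pSer keeps a slightly larger repulsive core (sigma 0.60 vs 0.518 nm),
  so `dU_P` is nonzero but small;
* **the enzyme is compact**, a single adsorption site: a larger bead
  cluster gives the anchor several adsorption positions separated by
  barriers, and slow surface hopping is again a hidden internal mode.
  With the 0.3 nm triangle the all-three-distances contact condition
  covers most of the bound ensemble, so phosphorylation chemistry acts
  nearly uniformly over the bound state;
* **identity exchange is uniform over the unbound ensemble**: the
  validation runs set the reservoir trigger to 2.5 nm, just outside the
  2 nm interaction cutoff, instead of the production default of half the
  box.  With a half-box trigger the unbound state splits into a near
  zone (no exchange possible) and a far zone (exchange active) whose
  interconversion by diffusion is slower than the lag; the chain-scale
  systems the method targets cover that diffusion time with their much
  longer lag, the desk-scale toy cannot;
* **neutral chemistry**: the toy pSer is uncharged; with the production
  -2 charge the 3.5 nm screened-Coulomb tail crosses any sensible
  bound/unbound boundary and the two chemical species see different
  long-range landscapes;
* **friction 1 ps^-1** for the substrate: a two-bead molecule has no
  internal bath to absorb the binding energy, so at the production
  0.001 ps^-1 it cannot be captured (ballistic in-and-out).  A long
  chain thermalizes binding through its own internal degrees of freedom;
  the toy borrows that role from the thermostat.  The integrator itself
  is unchanged;
* **attempt throttles** `phospho_interval = 60` and
  `reservoir_interval = 20` checks keep chemical conversion and identity
  exchange slower than the MSM lag of 25 Markov steps (one MC check
  each, 2 ps), so composite within-lag paths are rare.  Attempt
  frequency cancels from every rate ratio, so these throttles do not
  touch the thermodynamics;
* the bound/unbound assignment uses the **molecule-level binding
  coordinate** (minimum over both substrate beads of the active-site
  distances, threshold 1.8 nm), so an anchor-adsorbed pose with the Ser
  pointing away is never mislabeled unbound.

With these choices the cycle estimator recovers `dmu_cycle = dmu_P`
within two bootstrap standard errors at `dmu_P` = 0, -5 and -10 kJ/mol
from single 8e7-step runs (800 ns each, a few minutes on one core),
with the chemical edge shifting by the applied difference, the reservoir
edge exactly static and the binding edges static within error — the
acceptance suite re-runs exactly this.  The residual coarse-graining
bias visible at intermediate driving (of order 1 kJ/mol, toward zero) is
the textbook dissipation loss of lumping and shrinks as the timescale
separation grows; the chain-scale systems the method is built for sit
orders of magnitude deeper in the separated regime.

# Kinetics estimators

With at most one first-phosphorylation event per replica, the rate with a
uniform prior is `r_P = (n + 1)/Theta`, `var = (n + 1)/Theta^2`, where
`Theta` sums the event times plus `t_tot` for every censored replica.
The survival view is the *normalized inverse cumulative histogram*: each
bin holds its event count plus all later counts over the replica count.
Two least-squares models fit its shape: a single exponential
`exp(-r_P t)`, and a binding-conditioned process in which the observed
time is the sum of an exponential binding step (`r_B`) and an exponential
phosphorylation step, with complement
`r_B r_P/(r_B - r_P) (exp(-r_P t)/r_P - exp(-r_B t)/r_B)`.  The exchange
symmetry `r_B <-> r_P` is resolved by assigning the larger value to
`r_B`; the degenerate limit `r_B -> r_P` switches to the analytic form
`(1 + r t) exp(-r t)`; as `r_B -> infinity` the model collapses onto the
single exponential (checked numerically at ratio 1e4 to sup-norm 1e-3).
Fits are performed on log-rates by Nelder-Mead on the binned curve
normalized by its `t = 0` plateau, so right-censoring changes the plateau
but not the fitted shape.

Order statistics: for each ordered pair of serines, the probability that
one fires first is the win fraction over *decidable* replicas — both
observed, or exactly one observed, in which case the observed one counts
as first; double-censored replicas are excluded and pairs with no
decidable replica are masked.  This censoring convention is a package
choice (flagged in outputs) since aggregate counting over trajectories
with unfired serines can be done several ways.  The arrival-order
histogram counts, per replica in which a site fired, how many other sites
had already fired.  Contact rates count rising edges of the contact
criterion per unit time with the across-replica SEM, and
`rate_contact_correlation()` is the plain sample Pearson coefficient.

# Condensate analysis

`cluster_beads()` implements DBSCAN on minimum-image distances: beads
with at least `n_min` neighbours (excluding self) within `eps = 1` nm are
core; non-core beads attach iff they neighbour a core bead; expansion is
depth-first in ascending bead order, making labels deterministic.  The
test suite checks label-for-label agreement with scikit-learn's DBSCAN
(run on precomputed minimum-image distance matrices; its `min_samples`
counts the point itself, hence `min_samples = n_min + 1`) on 50 random
periodic configurations, and robustness of the largest-cluster chain set
over `eps` in [0.8, 3] nm and `n_min` in [2, 5] on a droplet-plus-gas
fixture.  A chain belongs to a cluster if any of its beads does (a
majority rule is available); the condensate is the cluster with most
chains, ties to the lowest label.  When classifying enzymes, the largest
cluster is determined among substrate chains only, so a detached enzyme
pair can never be "the condensate".  The condensate centre is the
per-axis circular mean, making every downstream profile invariant under
lattice translations; radial densities divide shell counts by
`4 pi/3 (r_out^3 - r_in^3)` with a default bin width of 0.5 nm (exposed).
Dissolution onset is the first frame below 97.5% of the initial plateau
(threshold exposed).  Per-residue energy decompositions attribute each
group-partner pair energy in full to the group residue, split into the
three pair terms; components sum to the total group-partner energy
exactly.

# Synthetic data and what the tests do (and do not) show

The generators define the study conditions of the test and acceptance
suites:

* `generate_markov_cycle()` — exact Gillespie sampling of a 4-state (or
  3-state) continuous-time cycle recorded at a fixed stride, with the
  analytic affinity stored; the oracle for the `dmu_cycle` estimator.
* `generate_exponential_events()` — censored single- or two-step
  exponential first-event times (N_sim = 1000 for the estimator study,
  N = 500 with `(r_B, r_P) = (20, 2)` per microsecond for the fit
  recovery), the oracle for the kinetics module.
* `generate_droplet_gas()` — a dense spherical cluster plus dispersed
  chains with ground-truth membership and assignable pSer counts, the
  fixture for clustering and profile tests, with overlap-free placement
  so the same configurations can seed engine runs.

Desk-scale engine studies replace the paper-scale campaigns: the
sequence-preference claim is tested as *aggregate C-terminal (Ser 369-410)
active-site contact rates exceeding N-terminal (Ser 266-350) ones* for the
real LCD sequence against a rigid Asp-Phe-Gly-Lys mini-kinase (three
1e6-step replicas in a 9 nm box, modified-HPS with the Yukawa cutoff at
2 nm where the screened tail is below 0.15 kJ/mol); and the dissolution
claim as *monotone loss of condensate chains with rising pSer fraction*
in a 10-chain droplet of sticky 12-bead model peptides driven at
-48 kJ/mol.  These reduced systems probe the same mechanisms (aromatic/
hydrophobic attraction to the catalytic face versus charge screening;
charge-driven solubilization of phosphorylated chains) but not the
quantitative rates, order probabilities or binding free energies of the
full-scale systems, which require cluster-scale compute and the
experimental kinase structure; nothing at desk scale validates those
numbers.

# Numerical choices and limitations

* Gas constant 0.00831446 kJ/(mol K); energies kJ/mol, lengths nm, times
  ps (so 1 kJ/mol = 1 amu nm^2/ps^2 and no unit conversion enters the
  integrator).
* The friction coefficient is applied per velocity component (units
  ps^-1), the literal reading of the force-field family's setup; it is a
  plain config field.
* Trajectory frames are plain TSV (long format, full-precision numbers)
  rather than a binary container: the installed R stack has no HDF5
  bindings, TSV round-trips bit-exactly, and desk-scale trajectories are
  small.  The writer/reader pair is round-trip tested.
* Bootstrap SEMs are standard deviations of circular block-bootstrap
  replicate distributions; estimator failures inside a replicate (e.g. an
  unvisited edge) drop that replicate rather than poisoning the SEM.
* The engine is single-threaded and deterministic for a fixed seed; the
  event log and final state reproduce bit-exactly.
* Autophosphorylation of the kinase's own disordered tail is outside the
  model, as is any secondary-structure coupling; folded-domain input
  coordinates (PDB 6RU7 / AlphaFold P48730) are user-supplied and never
  downloaded.
* The bundled kinase FASTA covers the catalytic domain (residues 1-294,
  active site Asp149-Phe150-Gly151); full-length fixtures error with
  fetch instructions.
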