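---
title: "The coarse-grained HNP chain model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coarse-grained HNP chain model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnpmd)
```

## The model

`hnpmd` simulates a single protein chain as a string of C-alpha beads drawn
from a three-letter alphabet: hydrophobic (H), neutral (N) and hydrophilic
(P). The twenty standard amino acids map onto these classes
(`classify_amino_acid()`): H = {Phe, Met, Ile, Leu, Trp, Val, Cys, Tyr},
N = {His, Ala, Gly, Thr}, P = {Lys, Asp, Asn, Glu, Gln, Ser, Pro, Arg}.
Study chains are periodic tilings of a repeat unit such as `H3N1P1`
(= HHHNP): the unit's hydrophobic fraction and its run of consecutive H
beads are the control variables of interest.

Four potential terms act on the chain (kcal/mol, nm, rad):

* **Stretch** `sum 1/2 kd (l_i - l0)^2` over bonds, with
  `l0 = 0.153` nm, `kd = 7e4` kcal/(nm^2 mol).
* **Bend** `sum 1/2 ktheta (theta_i - theta0)^2` over bond angles, with
  `theta0 = 1.231` rad, `ktheta = 100` kcal/(rad^2 mol). `theta` is the
  *deflection* angle between consecutive bond vectors; 1.231 rad = 70.53
  degrees is the supplement of the tetrahedral valence angle, so the
  equilibrium geometry is the familiar extended zigzag. (Reading 1.231 rad
  as the interior angle folds the chain onto itself, puts second-neighbor
  beads into deep steric overlap, and demonstrably breaks the equipartition
  behaviour of the bonded terms; the deflection reading satisfies it.)
* **Torsion** `sum 1/2 kphi (1 - cos 3 phi_i)` over dihedrals, with
  `kphi = 2.0` kcal/mol and `phi` measured from the trans state. The three
  minima are trans (`phi = 0`) and gauche+/- (`phi = +-2pi/3`), separated
  by barriers of height `kphi`. A dihedral counts as trans when
  `|phi| <= pi/3`.
* **Nonbonded** truncated 12-6 Lennard-Jones
  `4 eps(a,b) [(sigma/r)^12 - Lambda(a,b) (sigma/r)^6]` between beads at
  least four residues apart, `sigma = 0.3624` nm, cut at `Rc = 0.95` nm.
  The pair matrices make H-H the only attractive pair
  (`eps = eps_h = 0.1984` kcal/mol, `Lambda = 1`); N- and P-involved pairs
  are purely repulsive with reduced prefactors, and P-P carries
  `Lambda = -1` (soft extra repulsion). Temperatures are reported reduced:
  `T* = kB T / eps_h`.

Because every pair interaction except H-H is repulsive, chains with more
hydrophobic beads — and especially with longer consecutive H runs — gain
more cohesive energy, collapse into more compact globules, form more
long-range contacts and, at full equilibrium, order into bundles of
extended all-trans "stems".

### Numerical choices

* **Cutoff handling.** "Truncated" LJ is implemented truncate-and-shift
  (each pair potential is shifted to zero at `Rc`), keeping the energy
  continuous so microcanonical dynamics conserve it. Forces are unaffected.
  Absolute nonbonded energies are therefore offset from the plain-truncation
  spelling by a configuration-dependent constant bounded by
  `n_pairs * |u(Rc)|` (tiny: `|u(Rc)|` ~ 2e-3 kcal/mol for H-H).
  `pair_potential(..., shifted = FALSE)` exposes the raw form.
* **Units.** Simulation state is kept in real units (nm, nm/ps, g/mol,
  kcal/mol) with `1 kcal/mol = 4.184 amu nm^2/ps^2` as the only conversion
  constant; `kB = 1.9872e-3` kcal/(mol K). Reduced temperature converts via
  `tstar_to_kelvin()` (T* = 1 is ~99.8 K with the default `eps_h`).
* **Degenerate geometry.** Angle cosines are clamped to [-1, 1]; a
  collinear dihedral quadruplet is assigned `phi = 0` (trans) and
  contributes no torsional force. These are measure-zero configurations.
* **Pair exclusion.** "At least four residues apart" is `|i - j| >= 4` over
  unordered pairs; `|i - j| <= 3` pairs interact only through bonded terms.
  The contact definition (`|i - j| > lcut` with `lcut = 3`) matches it.

## Dynamics

`step_md()` advances the chain with velocity-Verlet. NVE (no thermostat) is
symplectic; the NVT path couples velocities to a single Nose-Hoover
thermostat via the Martyna-Tuckerman-Klein half-step splitting, with
coupling mass `Q = N_free kB T tau^2`, `tau = 25` fs, and
`N_free = 3N - 6` (net translation and rotation are projected out at
initialization by `remove_rigid_motion()` and conserved thereafter). The
default time step is 2.5 fs; the stiffest mode (bond stretch, period
~86 fs) is resolved by ~34 steps per period.

Validation highlights (all in the test suite):

* forces match central finite differences of the energy to better than
  1e-4 relative, satisfy Newton's third law and exert no net torque;
* a thermostatted 5-bead bonded-only chain reproduces exact canonical
  averages (quadrature oracles with the `l^2` and `sin theta` Jacobians)
  within ~1-2%;
* kinetic temperature holds to within 2% of target across T* 0.3-1.5;
* per-bond stretch and per-angle bend energies reach `kB T / 2` (5% band)
  at T* = 1.0 after ~5 ns of equilibration — the harmonic modes exchange
  energy only through anharmonic coupling, so this is the slowest
  equilibrating diagnostic in the model.

`run_quench()` realizes the production protocol: a seeded self-avoiding
random coil is generated at the first scheduled temperature
(`initial_configuration()`), thermalized, then each schedule leg retargets
the thermostat — a quench when the temperature drops. All randomness flows
from the protocol seed; identical seeds give bit-identical trajectories.

### The synthetic-data role

The sequence/configuration builder *is* the data generator: there is no
external input. Defaults mirror the study design — repeat units from
`H3N1P1` to `H8N4P4`, chain lengths 50-300, T* swept over 0.3-1.5,
per-bead mass 110 g/mol (mean residue mass; it only sets the time scale).
The initial coil draws bond angles uniformly in `theta0 +- 0.35` rad and
dihedrals uniformly in `(-pi, pi]`, subject to a `0.8 sigma` hard core
between nonbonded pairs. The angle window (rather than fully uniform
angles) is this package's choice: fully random deflections cost ~10 kBT
per angle and make self-avoiding placement of long chains unreliable,
while any initialization detail is erased by the high-temperature
thermalization leg. Velocities are Maxwell-Boltzmann with net momenta
projected out.

What the generator does *not* emulate: real amino-acid heterogeneity
(specific side-chain packing, electrostatics, hydrogen bonds, solvent), so
a green test establishes the behaviour of the HNP model, not of any
particular protein.

## Analysis

* `gyration()` — radius of gyration and principal-axis components
  (eigenvalues of the gyration tensor, ascending; `Rgz` is the long axis).
  `Rg^2 = Rgx^2 + Rgy^2 + Rgz^2` holds exactly (trace identity).
* `orientational_order()` — nematic order parameter
  `P = <(3 cos^2 a - 1)/2>` of bond vectors against the long axis; 1 =
  parallel, ~0 = isotropic, -0.5 = perpendicular. By default all N-1 bonds
  are averaged; `all_bonds = FALSE` reproduces the literal N-2 bond form
  (identical in the parallel/random limits used for calibration).
* `dihedral_states()` / `stems()` — trans/gauche classification
  (`|phi| <= pi/3`) and maximal all-trans runs. Following the
  dihedral-unit counting convention, a stem is a run of at least 4 trans
  dihedrals, each attributed to its central bond; an all-trans chain of N
  beads yields one stem of length N-3. Absolute stem lengths in
  bond-counting conventions differ by up to 2.
* `contact_count()` — pairs within `Rcut = 0.65` nm and `|i - j| > 3`.
* `sweep_summary()` — per-leg time averages with bootstrap standard errors
  (200 frame resamples, seeded); the first half of each leg is discarded as
  equilibration by default.

`run_experiment()` orchestrates the factorial study (units x lengths x
temperatures x seeds) with a JSON manifest keyed by a config hash, making
interrupted experiments resumable, and `compare_compositions()` ranks units
by any observable with bootstrap confidence intervals. Per-run sub-seeds
are derived deterministically from the config seeds (kept below 2^31).

## What a desk-scale run can and cannot reproduce

The reference results come from production runs of order 10^7 steps per
temperature. The tests and the acceptance suite scale this down to
1e5-5e5-step legs so the whole suite runs in minutes on one CPU. That
scale-down is safe for observables driven directly by the strength of the
H-H attraction:

* nonbonded energy per bond: H-richer units bind more strongly at fixed
  T* and N (reproduced, 3 seeds);
* contact counts: H-richer units form more long-range contacts
  (reproduced);
* compactness: H-richer units have smaller Rg (reproduced);
* composition monotonicity on a *frozen* frame — re-evaluating one
  low-temperature configuration under an H-richer sequence lowers the
  nonbonded energy — is exact, not statistical (reproduced);
* the high-temperature stem-length histogram decays near-geometrically
  (reproduced; note that at these run lengths the histogram support is
  narrow — lengths 4-6 dominate — because the collapsed globule suppresses
  long trans runs, so the check probes the decay, not its tail).

It is *not* safe for orientational order. The torsion barrier is
2.0 kcal/mol = 10 kBT at T* = 1.0 and 25 kBT at T* = 0.4: dihedral flips
run at ~0.5/ns per dihedral at T* = 1.0 and are frozen below T* ~ 0.6.
Stem/nematic ordering is a crystallization process that needs sustained
residence (tens to hundreds of ns, i.e. >= 2e7 steps) near the transition
region T* ~ 0.8-1.0. Desk-scale quenches — direct, annealed, or with 10 ns
transition-region legs — leave an amorphous globule with P ~ 0.02-0.12 at
every temperature and composition. The corresponding acceptance checks
(P rising as T* drops; P ranking H-richer units higher) are implemented at
the specified scale and deliberately left failing rather than weakened:
they document a genuine kinetic gap between desk-scale and production-scale
runs, not an implementation defect. (The full-scale stem-peak target — a
peak near 60 bonds for H4N1P1 at N = 240 — is likewise reachable only via
a long `ramp = TRUE` experiment, config-reachable but not part of the
default suite.)

## Known limitations

* No electrostatics, solvent, hydrogen bonding, or periodic boundaries
  (single chain in vacuum, as modeled).
* A single Nose-Hoover thermostat (no chains): kinetic temperature control
  is excellent, but equilibration of stiff-mode potential energies relies
  on slow anharmonic coupling; budget ~5 ns before trusting per-mode
  averages.
* The O(N^2) nonbonded evaluation is exact and fast enough for N <= 300 at
  desk scale; no cell lists.
* `stems()` lengths use dihedral units (see above) — comparisons against
  bond-unit conventions need the +-2 caveat.
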