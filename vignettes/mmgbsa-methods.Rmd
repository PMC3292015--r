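---
title: "Single-trajectory MM-GBSA: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trajectory MM-GBSA: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgbsa)
```

## The estimator

`mmgbsa` implements the end-state free-energy estimate used to rank
protein–ligand binding affinities from a simulation of the bound complex:

$$\Delta G_\text{bind} = \Delta G_\text{MM} + \Delta G_\text{sol} - T\Delta S$$

with the gas-phase molecular-mechanics part
$\Delta G_\text{MM} = \Delta E_\text{int} + \Delta G_\text{vdw} + \Delta G_\text{ele}$
and the solvation part
$\Delta G_\text{sol} = \Delta G_\text{pol} + \Delta G_\text{nopol}$,
$\Delta G_\text{nopol} = \gamma\,\mathrm{SASA} + \beta$.
Every $\Delta$ is `complex − receptor − ligand`, each species evaluated on
coordinates extracted from the *same* snapshot of the complex trajectory
(the single-trajectory protocol). Because all three species then share one
set of internal coordinates, $\Delta E_\text{int}$ cancels term by term;
`frame_delta_energies()` exploits this and evaluates the internal delta
directly from the (empty) set of partition-crossing bonded terms, so the
cancellation is exact to the last bit rather than "small".

Components are averaged over an ensemble of snapshots taken from the
trailing window of the trajectory (`select_snapshots()`, e.g. 200 snapshots
from the last 2 ns at 10 ps), with uncertainties reported as standard errors
of the mean, $SE = STD/\sqrt{N}$, using the sample (n−1) standard deviation
— the formula leaves the denominator convention open and the sample form is
the standard SE convention. The composite rows follow the usual bookkeeping:
$\Delta G_{\text{ele+pol}} = \Delta G_\text{ele} + \Delta G_\text{pol}$,
$\Delta G_\text{gb} = \Delta G_\text{vdw} + \Delta G_\text{nopol} +
\Delta G_{\text{ele+pol}}$, and
$\Delta G_\text{bind} = \Delta G_\text{gb} - T\Delta S$. The entropy term is
averaged over its own, much smaller snapshot set (see below) and enters the
table as the printed $-T\Delta S$ value with its own SE.

Experimental reference values are obtained from inhibition constants via
`ic50_to_dg()`, which returns $RT\ln(\mathrm{IC}_{50}/\text{mol L}^{-1})$:
the conventional magnitude conversion, signed so that sub-molar
concentrations map to favorable (negative) free energies, 1 M maps to zero,
and halving the IC50 lowers the result by $RT\ln 2$.

## Gas-phase terms

`coulomb_energy()` uses $k_e = 332.0637128$ kcal Å mol⁻¹ e⁻², the
mainstream molecular-mechanics value of the Coulomb constant.
`lj_energy()` is the 12-6 potential in $r_\text{min}$ form
($r_{\text{min},ij}$ additive, $\varepsilon_{ij}$ geometric), so a pair at
its combined minimum distance contributes exactly $-\varepsilon_{ij}$.
1-2 and 1-3 pairs are excluded; 1-4 pairs are divided by 1.2
(electrostatics) and 2.0 (van der Waals), the convention of the AMBER-family
force fields whose parameters the synthetic fixtures imitate. No distance
cutoff is applied: cutoffs belong to the MD engine, and end-state rescoring
conventionally uses full pairwise sums. A distance-dependent dielectric
$\varepsilon(r) = 4r$ is available as a mode switch; it is used when
minimizing snapshots for normal-mode analysis, where it mimics solvent
screening at negligible cost.

## Generalized Born polar solvation

`effective_born_radii()` implements pairwise descreening with the
tanh-rescaling correction: intrinsic radii are offset-reduced by 0.09 Å,
each neighbor descreens through the Hawkins–Cramer–Truhlar integral with its
scaled radius, and the effective radius is

$$R_i^{-1} = \tilde\rho_i^{-1} - \rho_i^{-1}
\tanh(\alpha\Psi - \beta\Psi^2 + \gamma\Psi^3).$$

Both published coefficient sets are provided; the default is the II variant
($\alpha=1.0,\ \beta=0.8,\ \gamma=4.85$), the canonical reading of a
"modified GB model" citation, with the I variant
($0.8,\ 0,\ 2.909125$) one `solvation_params(obc_variant = "OBC1")` away.
An isolated atom's effective radius is exactly its offset-reduced intrinsic
radius — the closed form used by the unit tests, alongside a
numerical-quadrature oracle that integrates $r^{-4}$ over a neighbor's
scaled sphere on a grid.

`gb_polar_energy()` is the pairwise energy with the canonical interpolation
$f_{GB} = \sqrt{r^2 + R_iR_j\exp(-r^2/4R_iR_j)}$, includes the $i=j$ Born
self terms, and uses interior/exterior dielectrics 1/80 with no salt
screening (zero ionic strength; nothing in the protocol invokes a Debye
term). A single ion reproduces the Born equation to machine precision.
Chlorine atoms, absent from common GB radius sets, default to an intrinsic
radius of 1.75 Å in the topology layer.

## Nonpolar solvation

`sasa()` is a Shrake–Rupley quadrature: 960 deterministic golden-spiral
points per solvent-expanded sphere (atom radius + 1.4 Å probe), a point
counting as accessible when outside every neighbor's expanded sphere.
Per-atom areas sum to the total by construction, which is what makes the
per-residue decomposition conservative. Against closed forms
(isolated sphere, two overlapping spheres) the quadrature is accurate to
well under 0.5%. At $\gamma = 0.0072$ kcal mol⁻¹ Å⁻² and $\beta = 0$, mesh
differences against other surface algorithms are far below 0.1 kcal/mol for
the buried-area differences that enter $\Delta G_\text{nopol}$.

## Per-residue decomposition and alanine scanning

`per_residue_decomposition()` attributes
$\Delta G_\text{vdw} + \Delta G_\text{ele} + \Delta G_\text{gb} +
\Delta G_\text{surf}$ to residues: pairwise terms (gas-phase and GB,
including self terms on the diagonal) are split half-and-half between the
two partner atoms — the convention of the decomposition scheme this method
family cites, which the source protocol leaves implicit — and per-atom
surface terms go to the owning residue. Summed over *all* residues
(both sides of the partition) every column reproduces the ensemble-mean
delta component exactly; this conservation is asserted for the wild type
and for every mutant in the test suite.

`mutate_to_alanine()` edits the wild-type trajectory rather than
re-simulating: the residue is truncated at the first side-chain heavy atom
beyond Cβ — one uniform rule, covering β-branched
residues, where "truncate at Cγ" is ambiguous — and that atom is
replaced by a hydrogen placed 1.09 Å (the standard aliphatic C–H length;
none is prescribed) from Cβ along the former bond vector in every
frame. Backbone and Cβ coordinates are untouched, the residue's
parameters are replaced from an alanine template
(`ala_template()`, overridable), and the new hydrogen clones the bonded
terms of an existing Cβ hydrogen. Proline (backbone incompatible
with alanine), glycine and alanine itself are rejected.
`alanine_scan()` re-runs the pipeline on the same snapshot set for each
mutant; the wild-type $-T\Delta S$ is reused (mutant entropies are not
re-evaluated — the reported changes are at the $\Delta G_\text{gb}$ level),
and residues whose inhibitor–residue interaction weakens by more than a
configurable 0.7 kcal/mol are flagged as hot spots.

## Structure metrics

`backbone_rmsd()` superposes each frame onto the reference (first frame by
default, standing in for the initial minimized structure) by the Kabsch
algorithm (SVD with a reflection guard, implemented in `kabsch_rmsd()`) over
the N/CA/C backbone, optionally including O. `hbond_occupancy()` counts a
frame when the heavy-donor–acceptor distance is < 3.5 Å *and* the
donor–H···acceptor angle measured at the hydrogen is > 120°; the
vertex-at-hydrogen reading is chosen because typical reported mean angles
(140–155°) are only consistent with that convention. Reported distance and
angle means are over qualifying frames only — the natural definition for a
table that describes the bonds that exist, at the price of being undefined
at zero occupancy (reported as `NA`).

## Normal-mode entropy

`binding_entropy()` estimates $-T\Delta S$ on a small snapshot subset (the
protocol's scale is 25 snapshots at 80 ps where the energy average uses
200): each species is minimized in the gas phase under the $4r$ dielectric
to a gradient RMS of 1e-4 kcal mol⁻¹ Å⁻¹, the mass-weighted Hessian is
diagonalized, and
$\Delta S = S_\text{complex} - S_\text{receptor} - S_\text{ligand}$ is
averaged with $SE = STD/\sqrt{N}$. Gas phase plus the $4r$ dielectric is
used for both the minimization and the Hessian, as the protocol is written.
Translational entropy is Sackur–Tetrode at 1 atm, rotational is the
classical rigid rotor (symmetry number 1, with the linear-molecule special
case), vibrational is the harmonic-oscillator sum per mode.

Numerical choices, made once and validated rather than tuned:

* **Minimizer** — rounds of L-BFGS-B on the analytic gradient, polished by
  modified-Newton steps (finite-difference Hessian, eigenvalue magnitudes in
  the denominator so the step stays a descent direction near weak saddles,
  rigid-body subspace projected out). Quasi-Newton alone stalls around RMS
  1e-2 in the ill-conditioned intermolecular valley; the Newton polish
  converges quadratically to the 1e-4 threshold. This replaces a
  steepest-descent/conjugate-gradient stage pairing with the same contract.
* **Hessian** — central finite differences of the analytic gradient, step
  1e-5 Å, symmetrized, for *all* terms (no analytic/FD hybrid). Validated
  against the diatomic closed-form frequency to 0.1% and symmetric to 1e-8.
* **Rigid modes** — the 6 modes of smallest magnitude (5 for linear
  molecules, detected from the inertia tensor) are dropped; any residual
  mode below 1 cm⁻¹ is also excluded. The threshold is a choice the source
  protocol leaves open; minimized fixtures show a clean gap
  (rigid modes < 0.1 cm⁻¹, softest genuine mode > 5 cm⁻¹).
* Frequencies from negative eigenvalues are reported as negative numbers; a
  mode below −5 cm⁻¹ raises a "not a minimum" error rather than being
  silently dropped.

## The synthetic fixtures

The generators in this package are first-class, tested code — they define
the study conditions for everything downstream.

`make_toy_complex()` builds a tripeptide-like receptor (three 13-atom
leucine-like residues, extended backbone $\varphi=-120°,\ \psi=140°$, built
by internal-coordinate placement) and a 9-atom amide-like ligand carrying
one chlorine (exercising the chlorine radius default), with full
charge/LJ/GB/bonded parameters of AMBER-like magnitude. The ligand's N–H
donor is constructed collinear with a backbone carbonyl of the middle
residue at N···O = 2.9 Å, giving a designed, backbone-mediated hydrogen
bond — the geometry that makes "mutation does not break a backbone H-bond"
testable. Bond/angle equilibria and dihedral phases are set from the built
geometry, so the base structure is near its own minimum and minimization is
well-behaved. Frames add isotropic Gaussian noise (default 0.03 Å, the
scale of tight thermal libration) under a private seeded RNG; the topology
is seed-independent.

`make_hbond_ensemble()` places the donor/acceptor triplet at designed
geometry: qualifying frames sample 2.8–3.0 Å and 150–160°, safely inside
the 3.5 Å/120° criteria; non-qualifying frames sit beyond 4.5 Å — margins
wide enough that floating point can never flip a frame's classification, so
designed occupancies are recovered *exactly*. `make_born_fixture()` is the
single-ion system for the Born closed form.

What these fixtures deliberately do not emulate: real force-field chemistry
(no torsional fitting, no aromatic systems), conformational transitions
(frames are noise around one basin), explicit-solvent artifacts, or the
size of a real protein complex. Tests passing on them demonstrate that the
estimator, decomposition, mutation editing and entropy machinery are
implemented correctly — not that any particular real system's absolute
numbers would be reproduced, which for the published systems would require
the original multi-nanosecond explicit-solvent trajectories. For the same
reason the published headline table is exercised through its *aggregation
arithmetic* (feeding printed component means through the composite
identities) rather than re-simulated; only its self-consistent cells are
used, and the two cells that disagree with their own row/column arithmetic
are excluded.

Problem sizes used in the shipped tests and acceptance script — 48-atom
complex, ensembles of 3–100 frames, 20-snapshot energy averages,
3-snapshot entropy averages — were chosen as the smallest sizes at which
every invariant is non-trivially exercised.

## Degenerate inputs and edge behavior

Interacting pairs closer than 1e-6 Å raise singularity errors (as do
coincident GB centers, with atom indices); angles with coincident atoms are
geometry errors. Zero-charge systems give exactly zero polar energy;
$\gamma = 0$ disables the nonpolar term; an ensemble without time stamps
falls back to index-based snapshot selection with a warning; selections
that split a residue, match nothing, or empty the receptor are rejected
before any computation. Mutating proline/glycine/alanine, or a residue
lacking the Cβ/Cγ pattern, is an error that names the
rule.

## Known limitations

* Single-trajectory protocol only; no separate receptor/ligand simulations.
* GB only — no Poisson–Boltzmann branch; no salt screening.
* No periodic boundary conditions, Ewald sums or constraints: this package
  post-processes ensembles, it does not generate them.
* Harmonic entropy only (no quasi-harmonic or interaction-entropy
  alternatives).
* The alanine template ships one parameter set; real force-field mutations
  would take their parameters from the force field's residue library via
  the same `ala_params` hook.
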