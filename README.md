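# mmgbsa

Single-trajectory **MM-GBSA** binding free-energy analysis in R, for
structural bioinformaticians who post-process molecular-dynamics ensembles
of receptor–ligand complexes: binding-energy tables with component
breakdowns, per-residue free-energy decomposition, computational alanine
scanning, hydrogen-bond occupancy and backbone-RMSD analysis — plus a
synthetic-fixture generator so the entire pipeline is testable without any
MD engine or external downloads.

## The method

The binding free energy is estimated from snapshots of the *complex*
trajectory (single-trajectory protocol):

```
ΔG_bind = ΔG_MM + ΔG_sol − TΔS
ΔG_MM   = ΔE_int + ΔG_vdw + ΔG_ele        (gas-phase molecular mechanics)
ΔG_sol  = ΔG_pol + ΔG_nopol               (implicit solvation)
ΔG_nopol = γ·SASA + β                     (γ = 0.0072 kcal·mol⁻¹·Å⁻², β = 0)
```

Every Δ is `complex − receptor − ligand` evaluated on coordinates from the
same frame, so ΔE_int cancels exactly. ΔG_pol comes from a generalized Born
model (pairwise descreening with tanh rescaling, dielectrics 1/80); SASA
from Shrake–Rupley quadrature; −TΔS from normal-mode analysis of snapshots
minimized under a distance-dependent dielectric ε(r) = 4r. Components are
reported as mean ± SE (= STD/√N) over the snapshot ensemble, with the
composite rows `ΔG_ele+pol = ΔG_ele + ΔG_pol`,
`ΔG_gb = ΔG_vdw + ΔG_nopol + ΔG_ele+pol` and `ΔG_bind = ΔG_gb − TΔS`.
Alanine scanning truncates a residue's side chain at the first heavy atom
beyond Cβ on the *existing* trajectory (no re-simulation) and re-scores;
hydrogen bonds count when the donor–acceptor distance is < 3.5 Å and the
D–H···A angle at the hydrogen exceeds 120°.

See the methods vignette (`vignettes/mmgbsa-methods.Rmd`) for the models,
numerical choices and the limits of what the synthetic fixtures demonstrate.

## Worked example

```r
library(mmgbsa)

tc   <- make_toy_complex(seed = 1, n_frames = 20)   # 48-atom toy complex
part <- partition_complex(tc$topology, ligand = "LIG")

comp <- ensemble_delta_energies(tc$ensemble, tc$topology, part)
ent  <- binding_entropy(tc$ensemble, tc$topology, part, frames = c(1, 10, 20))
tab  <- aggregate_energies(comp, minus_tds = ent$minus_tds,
                           minus_tds_se = ent$se)
print(tab)
```

```
MM-GBSA binding energies (kcal/mol, 20 snapshots)
    component  mean   se
          ele -6.27 0.11
          vdw -1.36 0.05
          pol  5.15 0.06
        nopol -0.77 0.00
 ele_plus_pol -1.12 0.05
           gb -3.24 0.05
    minus_TdS 11.45 0.21
         bind  8.21 0.22
```

Reading the table: the ligand's hydrogen bond and dispersion contacts are
favorable (ele −6.3, vdw −1.4 kcal/mol) and desolvation opposes them
(pol +5.2), giving an enthalpy-like binding term ΔG_gb of −3.2 kcal/mol;
for this 9-atom ligand, the entropic penalty of losing free translation and
rotation (+11.5) dominates, so the toy ligand would not bind — exactly the
size regime where the −TΔS term matters most.

The designed ligand-to-backbone hydrogen bond is recovered with full
occupancy and its geometry:

```r
hbond_occupancy(tc$ensemble, tc$topology,
                data.frame(donor = 40, hydrogen = 41, acceptor = 26))
```

```
    donor hydrogen acceptor mean_distance mean_angle occupancy
1 LIG4-N1  LIG4-H1   LEU2-O       2.89521   175.5289       100
```

Per-residue decomposition and an alanine scan of the receptor follow the
same objects:

```r
per_residue_decomposition(tc$ensemble, tc$topology, part)
alanine_scan(tc$ensemble, tc$topology, part, residues = 1:3)
```

`run_pipeline()` drives all stages from a single YAML configuration and
writes a deterministic report bundle (binding table, decomposition, scan,
RMSD, hydrogen bonds, provenance log).

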