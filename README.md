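# ppistab

Stability analysis of protein–protein complexes from structure ensembles
and molecular-dynamics-style trajectories, with MM-GBSA implicit-solvent
binding-enthalpy scoring.

`ppistab` is aimed at structural bioinformaticians who want to judge
whether a bound partner (a peptide fragment, an interaction motif, a
grafted model) stays put on its receptor, and how strongly it binds — the
workflow that arises when an interaction region is only partially resolved
in crystal structures and has to be completed computationally before its
behaviour can be compared with that of the crystallographic fragment. The
running example throughout the package is a kinase-domain receptor whose
partners dock onto either its N-terminal lobe or its central lobe.

The package provides:

* **Structure/trajectory I/O** — PDB reading and writing (multi-MODEL
  files become trajectories), highest-occupancy altloc resolution, water
  dropping, residue-range selections (`"B:7-43,61-89"`), and partner
  bookkeeping (residue and heavy-atom counts).
* **Ensemble PCA ("essential dynamics")** — Kabsch superposition, 2D-RMSD
  maps, common-core extraction across incomplete ensemble members,
  coordinate PCA of Cα positions via SVD, and eigenvalue-weighted
  per-residue fluctuation profiles that reduce exactly to the RMSF when
  all components are kept.
* **Model completion** — grafting a missing partner fragment onto a
  template backbone, sequence mutation with idealized Cβ sidechains, and
  ideal-geometry terminus extension (extended or helical), with steric
  clashes reported rather than silently fixed.
* **Interface metrics** — residue contact maps (heavy-atom or Cα mode),
  start-vs-end Cα separation maps, Cβ–Cβ distance series and
  distributions, salt-bridge minima over charged-group atoms, and
  persistence fractions.
* **Tunnel proximity** — engagement of the partner with named receptor
  surface tunnels specified by their lining residues (packaged Aurora A
  kinase-domain definitions included).
* **MM-GBSA scoring** — intermolecular Coulomb + Lennard-Jones energies,
  generalized-Born (OBC-II) polar solvation with HCT pairwise
  descreening, LCPO surface-area nonpolar solvation, multi-pose averaging
  over the last half of a trajectory, and per-heavy-atom ligand
  efficiency.
* **Synthetic data** — seeded generators for ideal peptides, two-chain
  complexes at a prescribed gap, ensembles with planted orthonormal
  modes, bound (jitter) and dissociating (rigid drift) trajectories, and
  closed-form charge/sphere systems used to validate every energy term.

## The model

Binding enthalpy is composed by the standard single-trajectory MM-GBSA
cycle,

    ΔG_bind = ΔG_complex − (ΔG_receptor + ΔG_partner)
    ΔG      = ΔE_MM + ΔG_solv,   ΔG_solv = ΔG_polar + ΔG_nonpolar

with the entropy term omitted. Because receptor and partner conformations
are extracted from the same complex frame, intramolecular bonded terms
cancel and `ΔE_MM` reduces to the intermolecular Coulomb and 12-6
Lennard-Jones energies. `ΔG_polar` is the generalized-Born energy

    ΔG_polar = −½ (1/ε_in − 1/ε_solv) k Σ_ij q_i q_j / f_GB(r_ij, R_i, R_j)

with effective radii `R_i` from the OBC-II tanh rescaling of HCT pairwise
descreening sums, and `ΔG_nonpolar = γ·SASA` with the surface area from
the LCPO pairwise-overlap expansion. Multi-pose scores are reported in
kJ/mol as mean ± SD over poses evenly spaced through the last half of the
trajectory, and ligand efficiency is the mean divided by the partner's
heavy-atom count.

## Worked example

```r
library(ppistab)

rec <- build_toy_peptide("KLLALALLALAL", "helical",  chain = "A", start = 101)
par <- build_toy_peptide("ELLALLA",      "extended", chain = "B", start = 61)
cx  <- make_complex(rec, par, gap = 4, axis = c(0, 0, 1), label = "toy helix complex")
fragment_stats(cx$structure, cx$cdef)
#> $n_residues
#> [1] 7
#> $n_heavy_atoms
#> [1] 35

traj <- trajectory_bound(cx$structure, sigma = 0.2, n_frames = 100, seed = 1)
sep  <- separation_change(traj, cx$cdef)
range(sep)                      # -0.98 .. 0.94 A: no net separation
score <- multi_pose_score(traj, cx$cdef, toy_params(cx$structure), n_poses = 5)
score
#> <binding_score> toy helix complex
#>   dG = -5.61 +/- 0.45 kJ/mol over 5 poses (frames 51,63,75,87,99)
#>   35 heavy atoms, LE = -0.16 kJ/mol per heavy atom

dis <- trajectory_dissociating(cx$structure, "B", drift = c(0, 0, 0.05),
                               sigma = 0, n_frames = 100, seed = 1)
min(separation_change(dis, cx$cdef))
#> [1] -4.95
```

The bound trajectory shows a fluctuation-sized separation map and a
favourable (negative) binding enthalpy; the dissociating trajectory shows
the diagnostic signature of a partner leaving: every receptor–partner Cα
pair separates, with pairs along the drift axis separating by exactly
`(n_frames − 1) × drift = 4.95 Å`.

The same analysis runs end-to-end from a config file:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "ppistab"),
             "demo_out")
```

which writes `structures/`, `metrics/` (contact map, separation map,
distance series, tunnel proximity), `scores/binding_score.json` and a
`logs/run.log` recording every cutoff and seed actually used. A thin CLI
wrapper lives at `inst/cli/ppistab.R`.

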