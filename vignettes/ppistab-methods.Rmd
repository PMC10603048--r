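---
title: "Methods and design notes for ppistab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ppistab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppistab)
```

`ppistab` judges the stability of a receptor–partner complex from three
angles: how the ensemble of available structures varies (coordinate PCA),
whether the partner stays on the receptor over a trajectory (interface
and tunnel metrics), and how strongly it binds (MM-GBSA enthalpy
scoring). This vignette records the models behind each stage, the
tunable parameters with their defaults, the numerical choices, and what
the synthetic test bed does and does not demonstrate.

## Ensemble PCA and fluctuation profiles

Each ensemble member contributes a 3N vector of Cα coordinates over a
*common core*: the residues carrying a Cα in every member, minus any
excluded ranges. The exclusion is configuration, not a constant, because
which residues are unresolved differs between ensembles (a mobile
activation loop is the canonical case for kinase-domain ensembles).

Superposition precedes covariance. Members are first fitted onto a
reference member (default: the first), then twice onto the recomputed
ensemble mean. The two mean-fit iterations are the standard
essential-dynamics convention: the result no longer depends on which
member is chosen as the initial reference (the eigenvalue spectrum is
rigid-motion invariant to ~1e-6, and the test suite asserts this).
The mean-centred coordinate matrix is decomposed by SVD rather than by
eigendecomposition of the 3N×3N covariance; this is numerically stabler
and never forms the covariance explicitly. Eigenvalues are sample
covariance eigenvalues (divisor n−1), in Å².

Per-residue fluctuation profiles aggregate the first *k* principal
components as

$$f_i = \sqrt{\sum_{j \le k} \lambda_j\, \lVert \ell_j(i) \rVert^2}$$

where $\ell_j(i)$ is residue *i*'s 3-vector loading on component *j*.
The default *k* = 5 summarises the dominant motions; the formula is
chosen so that with *k* equal to the number of components it is exactly
the RMSF about the ensemble mean — an identity the tests verify to 1e-6,
which pins the eigenvalue scaling and the aggregation down jointly.

## Model completion

A missing partner fragment is completed in three steps, none of which
performs energy minimization:

* **Grafting** copies the backbone (N, Cα, C, O) of a template segment
  verbatim, so the grafted backbone coincides with the template by
  construction, and assigns new residue identities and author numbering.
* **Mutation** keeps the backbone and replaces the sidechain with an
  idealized Cβ at 1.53 Å from the Cα in the tetrahedral direction
  defined by the N–Cα–C frame (omitted for glycine). L-chirality is
  enforced: the signed volume of (N, C, Cβ) about the Cα is positive,
  equivalent to a N–C–Cα–Cβ torsion of +122.6°.
* **Terminus extension** builds residues with ideal trans-peptide
  geometry (N–Cα 1.46 Å, Cα–C 1.52 Å, C–N 1.33 Å, ω = 180°), with
  φ/ψ = (−140°, 135°) for extended and (−57°, −47°) for helical
  conformations, by internal-coordinate (NeRF) chain extension in either
  direction.

Sidechains beyond Cβ are deliberately not built: every downstream metric
in the package is Cα/Cβ based, rotamer placement would demand a
force-field and refinement machinery out of scope here, and a Cβ-only
model is honest about what it knows. For the same reason nothing is
relaxed after building; instead, heavy-atom clashes below 2 Å against
the rest of the structure are collected by a brute-force pair scan and
attached to the result for the caller to inspect. The junction between a
grafted fragment and pre-existing residues is likewise not closed by
force; the junction bond length is whatever the geometry gives, and
reporting it honestly beats pretending a loop-closure algorithm ran.

## Interface metrics

* **Contact maps** mark a residue pair in contact when its minimum
  inter-residue distance is strictly below the cutoff (default 5 Å).
  The default atom set is all heavy atoms — the field convention — with
  a Cα mode for backbone/Cβ-only models; both are exposed because
  figure-level contact maps in the literature rarely state the atom set.
* **Separation maps** use only two frames by design: Δd = d(first) −
  d(last) per receptor–partner Cα pair, positive when the pair
  approaches. A two-snapshot design is deliberately coarse (and can
  mislead if either endpoint is atypical); it is kept because it answers
  the specific question "did the partner keep its pose?" cheaply and
  reproducibly. Distances are internal, so the map is invariant to rigid
  whole-frame motion and needs no superposition.
* **Salt bridges** take the per-frame minimum over carboxylate oxygens
  (OD1/OD2/OE1/OE2) × basic nitrogens (NZ, NH1/NH2/NE). The 4 Å N–O
  cutoff and the 0.5 persistence threshold are standard literature
  values, both configurable, since "persistent" is rarely quantified in
  publications. Cβ-only models fall back to Cβ–Cβ distances and the
  series is flagged as a surrogate rather than silently rebranded.
* **Tunnel proximity** measures the minimum Cβ–Cβ distance from a
  partner residue to a named set of receptor residues. Tunnel detection
  itself (pocket volumes, bottleneck radii) is out of scope; tunnels are
  inputs, and the packaged kinase-domain definitions are ordinary data.
  The engagement threshold defaults to 8 Å, midway between the tight
  (~5 Å) and loose ("as high as 10 Å") distance regimes such
  distributions display; it is a reporting device, not a physical claim.

## MM-GBSA scoring

The enthalpy composition follows the single-trajectory convention:
complex, receptor and partner conformations come from the same frame, so
intramolecular bonded terms cancel exactly and the molecular-mechanics
part reduces to intermolecular Coulomb + Lennard-Jones. The tests
enforce this cancellation by recomposing the binding energy from
independently scored species.

Parameters and defaults, all configurable:

| parameter | default | units | role |
|---|---|---|---|
| interior dielectric ε_in | 1 | — | Coulomb and GB prefactor |
| solvent dielectric ε_solv | 78.5 | — | GB prefactor |
| nonbonded cutoff | 18 | Å | Coulomb/LJ pair sums |
| GB offset | 0.09 | Å | reduced intrinsic radius |
| OBC α, β, γ | 1.0, 0.8, 4.85 | — | tanh rescaling (OBC-II) |
| SASA probe | 1.4 | Å | solvent radius |
| surface tension γ | 0.005 | kcal/mol/Å² | nonpolar term |
| poses | 5 | — | multi-pose averaging |
| salt concentration | 0 | M | no Debye screening term |

Numerical notes:

* The Coulomb constant is 332.0637 kcal·Å/mol/e². Energies are kcal/mol
  internally and ×4.184 (kJ/mol) in reported binding scores.
* The GB pair sum applies **no** distance cutoff: the screened 1/f_GB
  cross terms are long-ranged physics, and the distant-ion-pair test
  (agreement with screened Coulomb to 0.1% at 50 Å) would be destroyed
  by one. The 18 Å cutoff applies to the MM terms only.
* Effective Born radii use HCT pairwise descreening integrals with an
  optional per-atom screening factor (default 1), rescaled by the OBC-II
  tanh formula. An isolated atom reduces exactly to ρ − 0.09 Å, and a
  Monte-Carlo evaluation of the descreening volume integral reproduces
  the analytic radii to ~1e-3 in the tests.
* LCPO surface areas use the full four-term pairwise-overlap expansion
  with per-atom coefficients. The auto-assigned toy coefficients
  (1, −1, 0, 0) truncate to the two-body expansion, which is *exact* for
  isolated atoms and sphere pairs — precisely the cases with closed
  forms — and over-buries densely packed interiors, where per-atom
  values clamp at zero. Users scoring full-atom structures should supply
  fitted coefficients through the parameter table.
* Of the two solvation components, the generalized-Born term is the
  polar one and the LCPO/SASA term the nonpolar one; descriptions that
  attach the GB model to the nonpolar component conflate the two, and
  the package follows the standard reading.
* Pose frames are spaced evenly over the last half: first candidate
  ⌊n/2⌋+1, step ⌊(n − first)/(poses − 1)⌋, so a 100-frame trajectory
  with 5 poses scores frames 51, 63, 75, 87, 99. Even spacing is a
  choice; any rule sampling the last half reproducibly would do.
* Ligand efficiency divides the mean of the *per-pose* binding
  enthalpies (not a static-model value) by the partner heavy-atom count
  and rounds half-away-from-zero to two decimals — the convention that
  makes the published per-construct efficiencies internally consistent.
* Optional pose relaxation is a **rigid-body** adjustment of the partner
  (6 degrees of freedom against the intermolecular MM energy), off by
  default. A Cartesian minimizer was considered and rejected: the energy
  function carries no bonded terms, so free-atom descent would distort
  covalent geometry. Rigid-body relaxation polishes the pose while
  leaving all internal geometry untouched.
* Toy parameter auto-assignment places unit charges on Lys/Arg (+1) and
  Asp/Glu (−1) — on the charged-group atom when present, else the Cβ —
  with element-based LJ parameters and mbondi-like GB radii. This is a
  validation vehicle, not a force field: all quantitative checks in the
  package are closed-form limits or published arithmetic, never absolute
  energies of the toy systems.

## Synthetic data: what it shows and what it cannot

The generators emulate exactly three phenomena: coordinate variance
concentrated on planted orthonormal modes (for PCA recovery), stationary
Gaussian jitter around a bound pose, and rigid progressive drift of one
chain (dissociation). Planted modes are projected onto the complement of
the rigid-body subspace before use (`orthonormal_modes()`), because
superposition removes rigid motion and any rigid component of a planted
mode would be silently lost — the recovered variance fractions would
otherwise be biased low.

Passing tests on this bed demonstrates that the *machinery* is correct:
superposition, covariance, eigenstructure, distance bookkeeping, energy
composition, seeded reproducibility. It does not demonstrate anything
about real molecular dynamics: the jitter has no covariance structure,
the drift has no force behind it, solvent and sidechains are absent, and
binding enthalpies of Cβ-only toys are not comparable to published
values computed with full force fields on microsecond trajectories.
The package therefore validates against closed forms (Born ion, screened
Coulomb, sphere surface areas, Lennard-Jones minima), brute-force
re-enumeration, and published arithmetic identities (efficiency =
mean/atoms), never against absolute published energies.

Problem sizes in the tests were chosen to keep the full suite fast while
leaving the statistics meaningful: 500-member ensembles for variance
recovery (±0.03 absolute), 1000-frame trajectories for jitter SD checks
(±10–15%), and ≤50-atom instances wherever a brute-force oracle runs in
a double loop.

## Degenerate inputs and tie-breaks

* Altloc resolution keeps the highest-occupancy conformer; ties prefer
  altloc "A". This makes parsing deterministic.
* Residue identity is (chain, author number, insertion code)
  throughout; author numbering is what publications quote.
* Hydrogens are accepted on input but excluded from analysis selections;
  waters and common monatomic ions are dropped on read by default while
  HETATM ligands (nucleotides, inhibitors) are retained.
* An ensemble of identical structures has zero variance and PCA refuses
  it explicitly rather than returning NaN fractions.
* `closest_partner_residue` breaks exact median ties by the lower
  residue number.
* Zero-length terminus extensions and same-name mutations are no-ops.
* PDB coordinates beyond the fixed-width field (−999.999..9999.999 Å)
  are an error on write, not a silent truncation.

## Known limitations

* Cβ-only completion: no rotamers, no loop closure, no refinement.
* The two-snapshot separation map inherits the coarseness of its design;
  a windowed variant would average endpoint noise but is not the default
  because the two-snapshot answer is the one figure-level analyses use.
* LCPO with the toy coefficient set saturates (clamps to zero) inside
  dense cores; fitted per-type coefficients are needed for quantitative
  areas of full-atom structures.
* No entropy term anywhere: scores are binding *enthalpies*, and for
  intrinsically disordered partners the missing −TΔS can be large.
* No salt screening in the GB term (zero ionic strength).
* PCA is Cα-only by construction; ligands and sidechains never enter the
  covariance.
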