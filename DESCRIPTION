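Package: ppistab
Title: Stability Analysis of Protein-Protein Complexes from Structure Ensembles and Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging the stability of protein-protein complexes from
    coordinate ensembles and molecular-dynamics-style trajectories. Provides
    ensemble principal component analysis of C-alpha coordinates with
    eigenvalue-weighted per-residue fluctuation profiles, template-based
    grafting and ideal-geometry extension of missing partner fragments,
    interface contact maps, start-versus-end backbone separation maps,
    C-beta distance distributions and salt-bridge persistence, proximity
    analysis against named surface-tunnel residue sets, and MM-GBSA
    implicit-solvent binding-enthalpy scoring (generalized Born OBC polar
    term, LCPO surface-area nonpolar term) with multi-pose averaging and
    per-heavy-atom ligand-efficiency normalization. Includes seeded
    synthetic-data generators (planted-mode ensembles, bound and
    dissociating two-chain trajectories, closed-form charge systems) so the
    whole pipeline can be exercised and validated without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
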