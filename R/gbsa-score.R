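# MM-GBSA binding-enthalpy composition: single-trajectory convention
# (receptor and partner conformations are extracted from the complex
# frame, so intramolecular bonded terms cancel exactly and the molecular
# mechanics part reduces to intermolecular Coulomb + LJ), multi-pose
# averaging over the last half of a trajectory, and per-heavy-atom ligand
# efficiency.  The entropy term is omitted by design.

new_energy_breakdown <- function(e_elec, e_vdw, g_polar, g_nonpolar) {
  structure(list(e_elec = e_elec, e_vdw = e_vdw, g_polar = g_polar,
                 g_nonpolar = g_nonpolar,
                 total = e_elec + e_vdw + g_polar + g_nonpolar),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (kcal/mol | kJ/mol)\n")
  for (f in c("e_elec", "e_vdw", "g_polar", "g_nonpolar", "total"))
    cat(sprintf("  %-10s %10.3f | %10.3f\n", f, x[[f]],
                x[[f]] * KCAL_TO_KJ))
  invisible(x)
}

species_solvation <- function(xyz, p, eps_in, eps_solv, gamma) {
  radii <- effective_born_radii(xyz, p$gb_radius, p$screen)
  gp <- gb_polar_energy(xyz, p$charge, radii, eps_in, eps_solv)
  sasa <- lcpo_sasa(xyz, p$lcpo_radius, p$lcpo_p1, p$lcpo_p2, p$lcpo_p3,
                    p$lcpo_p4)$total
  list(g_polar = gp, g_nonpolar = nonpolar_energy(sasa, gamma))
}

#' MM-GBSA binding enthalpy of a complex frame
#'
#' `dG_bind = G(complex) - G(receptor) - G(partner)` with all three species
#' taken from the same frame.  The molecular-mechanics part is the
#' intermolecular Coulomb + LJ energy (intramolecular terms cancel under
#' the single-trajectory convention); the solvation part is the difference
#' of GB polar and LCPO/SASA nonpolar terms between the complex and the
#' separated species.
#'
#' @param frame a `ppi_structure` (one complex pose).
#' @param cdef a `complex_def`.
#' @param params an `atom_params` table (see [read_atom_params()],
#'   [toy_params()]).
#' @param cutoff nonbonded cutoff (A) for the MM terms.
#' @param eps_in,eps_solv interior/solvent dielectrics.
#' @param gamma SASA surface tension (kcal/mol/A^2).
#' @return an `energy_breakdown` (kcal/mol).
#' @export
binding_energy <- function(frame, cdef, params, cutoff = 18,
                           eps_in = 1, eps_solv = 78.5, gamma = 0.005) {
  rec <- selection_indices(frame, cdef$receptor, hydrogens = TRUE)
  par <- selection_indices(frame, cdef$partner, hydrogens = TRUE)
  if (length(intersect(rec, par)) > 0) stopf("overlapping selections")
  if (length(rec) == 0 || length(par) == 0) stopf("empty selection")
  p <- align_params(frame, params)
  xyz <- xyz_to_mat(structure_xyz(frame))

  e_elec <- coulomb_energy(xyz, p$charge, rec, par, cutoff)
  e_vdw <- lj_energy(xyz, p$eps, p$rmin, rec, par, cutoff)

  all_idx <- c(rec, par)
  sc <- species_solvation(xyz[all_idx, , drop = FALSE],
                          p[all_idx, , drop = FALSE], eps_in, eps_solv, gamma)
  sr <- species_solvation(xyz[rec, , drop = FALSE], p[rec, , drop = FALSE],
                          eps_in, eps_solv, gamma)
  sl <- species_solvation(xyz[par, , drop = FALSE], p[par, , drop = FALSE],
                          eps_in, eps_solv, gamma)
  new_energy_breakdown(e_elec, e_vdw,
                       sc$g_polar - sr$g_polar - sl$g_polar,
                       sc$g_nonpolar - sr$g_nonpolar - sl$g_nonpolar)
}

# Evenly spaced pose frames over the last half of a trajectory (1-based):
# first candidate floor(n/2) + 1, step floor((n - first) / (n_poses - 1)).
pose_frames <- function(nf, n_poses) {
  if (nf < 2 * n_poses) stopf("too few frames (%d) for %d poses", nf, n_poses)
  first <- nf %/% 2 + 1L
  if (n_poses == 1) return(first)
  step <- (nf - first) %/% (n_poses - 1L)
  first + step * (seq_len(n_poses) - 1L)
}

#' Multi-pose MM-GBSA binding score
#'
#' Scores `n_poses` frames evenly spaced over the last half of the
#' trajectory and reports their mean and standard deviation in kJ/mol,
#' together with the partner heavy-atom count and ligand efficiency.
#' Optionally, each pose is first relaxed by a rigid-body adjustment of the
#' partner (6 degrees of freedom, minimising the intermolecular
#' Coulomb + LJ energy); covalent geometry is never altered.
#'
#' @inheritParams binding_energy
#' @param trajectory a `ppi_trajectory` with at least `2 * n_poses` frames.
#' @param n_poses number of poses (default 5).
#' @param relax apply rigid-body pose relaxation before scoring?
#' @return a `binding_score`: per-pose kJ/mol values, `mean`, `sd`,
#'   `frames`, `n_heavy_atoms`, `ligand_efficiency`.
#' @export
multi_pose_score <- function(trajectory, cdef, params, n_poses = 5,
                             relax = FALSE, cutoff = 18, eps_in = 1,
                             eps_solv = 78.5, gamma = 0.005) {
  frames <- pose_frames(n_frames(trajectory), n_poses)
  per_pose <- vapply(frames, function(f) {
    fr <- frame_structure(trajectory, f)
    if (relax) fr <- relax_pose(fr, cdef, params, cutoff)
    binding_energy(fr, cdef, params, cutoff, eps_in, eps_solv,
                   gamma)$total * KCAL_TO_KJ
  }, numeric(1))
  n_heavy <- fragment_stats(trajectory$topology, cdef)$n_heavy_atoms
  mu <- mean(per_pose)
  structure(list(per_pose = per_pose, frames = frames, mean = mu,
                 sd = stats::sd(per_pose), n_heavy_atoms = n_heavy,
                 ligand_efficiency = ligand_efficiency(mu, n_heavy),
                 label = cdef$label),
            class = "binding_score")
}

#' @export
print.binding_score <- function(x, ...) {
  cat(sprintf("<binding_score> %s\n  dG = %.2f +/- %.2f kJ/mol over %d poses (frames %s)\n  %d heavy atoms, LE = %.2f kJ/mol per heavy atom\n",
              x$label, x$mean, x$sd, length(x$per_pose),
              paste(x$frames, collapse = ","), x$n_heavy_atoms,
              x$ligand_efficiency))
  invisible(x)
}

# rigid-body relaxation of the partner: optimise rotation (xyz Euler
# angles about the partner centroid) + translation against the
# intermolecular Coulomb + LJ energy
relax_pose <- function(frame, cdef, params, cutoff = 18) {
  rec <- selection_indices(frame, cdef$receptor, hydrogens = TRUE)
  par <- selection_indices(frame, cdef$partner, hydrogens = TRUE)
  p <- align_params(frame, params)
  xyz <- xyz_to_mat(structure_xyz(frame))
  cen <- colMeans(xyz[par, , drop = FALSE])
  apply_rb <- function(theta) {
    ang <- theta[1:3]; tr <- theta[4:6]
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rot <- matrix(c(cy * cz, cy * sz, -sy,
                    sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
                    cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
                  3, 3, byrow = TRUE)
    out <- xyz
    out[par, ] <- sweep(sweep(xyz[par, , drop = FALSE], 2, cen) %*% t(rot),
                        2, cen + tr, `+`)
    out
  }
  obj <- function(theta) {
    m <- apply_rb(theta)
    coulomb_energy(m, p$charge, rec, par, cutoff) +
      lj_energy(m, p$eps, p$rmin, rec, par, cutoff)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "L-BFGS-B",
                      lower = c(rep(-0.2, 3), rep(-1.5, 3)),
                      upper = c(rep(0.2, 3), rep(1.5, 3)),
                      control = list(maxit = 100))
  set_structure_xyz(frame, mat_to_xyz(apply_rb(fit$par)))
}

#' Ligand efficiency per heavy atom
#'
#' Mean binding enthalpy divided by the partner heavy-atom count, rounded
#' half-away-from-zero to two decimals (kJ/mol per heavy atom).
#'
#' @param mean_dg mean binding enthalpy (kJ/mol).
#' @param n_heavy partner heavy-atom count (> 0).
#' @return ligand efficiency, 2 decimals.
#' @export
ligand_efficiency <- function(mean_dg, n_heavy) {
  if (n_heavy <= 0) stopf("heavy-atom count must be positive")
  x <- mean_dg / n_heavy
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}
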