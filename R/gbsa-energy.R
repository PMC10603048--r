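# MM-GBSA energy terms: Coulomb and Lennard-Jones molecular mechanics,
# generalized-Born (OBC-II) polar solvation with HCT pairwise descreening,
# and LCPO surface-area based nonpolar solvation.  All energies in kcal/mol
# internally; kJ/mol (x 4.184) for reported binding scores.

COULOMB_K <- 332.0637
KCAL_TO_KJ <- 4.184

# pair index matrix: all i<j within `idx`, or all cross pairs (ia, ib)
pair_set <- function(idx_a, idx_b = NULL) {
  if (is.null(idx_b)) {
    n <- length(idx_a)
    if (n < 2) return(cbind(integer(0), integer(0)))
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    cbind(idx_a[ut[, 1]], idx_a[ut[, 2]])
  } else {
    as.matrix(expand.grid(idx_a, idx_b, KEEP.OUT.ATTRS = FALSE))
  }
}

pair_distances <- function(xyz, pairs) {
  sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                xyz[pairs[, 2], , drop = FALSE])^2))
}

#' Coulomb energy over a pair set
#'
#' `sum 332.0637 q_i q_j / r_ij` (kcal/mol) over either all unique pairs
#' within `group_a` or all cross pairs between `group_a` and `group_b`,
#' with a nonbonded distance cutoff (default 18 A; `Inf` disables it).
#'
#' @param xyz N x 3 coordinate matrix (A).
#' @param charge per-atom charges (e).
#' @param group_a,group_b atom index vectors; `group_b = NULL` means all
#'   pairs within `group_a`.
#' @param cutoff nonbonded cutoff (A).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(xyz, charge, group_a = seq_len(nrow(xyz)),
                           group_b = NULL, cutoff = 18) {
  pairs <- pair_set(group_a, group_b)
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(xyz, pairs)
  if (any(r < 1e-9)) stopf("coincident atoms in Coulomb sum")
  keep <- r <= cutoff
  sum(COULOMB_K * charge[pairs[keep, 1]] * charge[pairs[keep, 2]] / r[keep])
}

#' Lennard-Jones 12-6 energy over a pair set
#'
#' Lorentz-Berthelot combining of per-atom well depths `eps` (kcal/mol) and
#' `rmin` half-minimum radii (A): `Rmin_ij = rmin_i + rmin_j`,
#' `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @inheritParams coulomb_energy
#' @param eps,rmin per-atom LJ parameters.
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(xyz, eps, rmin, group_a = seq_len(nrow(xyz)),
                      group_b = NULL, cutoff = 18) {
  if (any(rmin <= 0)) stopf("nonpositive LJ radius")
  pairs <- pair_set(group_a, group_b)
  if (nrow(pairs) == 0) return(0)
  r <- pair_distances(xyz, pairs)
  keep <- r <= cutoff
  pairs <- pairs[keep, , drop = FALSE]; r <- r[keep]
  rm_ij <- rmin[pairs[, 1]] + rmin[pairs[, 2]]
  e_ij <- sqrt(eps[pairs[, 1]] * eps[pairs[, 2]])
  x6 <- (rm_ij / r)^6
  sum(e_ij * (x6^2 - 2 * x6))
}

# HCT pairwise descreening integral for atom i (reduced radius rho_t)
# against neighbour spheres of scaled radius s at distances r.
hct_integral <- function(rho_t, s, r) {
  total <- 0
  for (k in seq_along(r)) {
    rk <- r[k]; sk <- s[k]
    if (rho_t >= rk + sk) next        # neighbour buried inside atom i
    l <- max(rho_t, abs(rk - sk))
    u <- rk + sk
    term <- 0.5 * (1 / l - 1 / u + rk / 4 * (1 / u^2 - 1 / l^2) +
                   1 / (2 * rk) * log(l / u) +
                   sk^2 / (4 * rk) * (1 / l^2 - 1 / u^2))
    if (rho_t < sk - rk) term <- term + (1 / rho_t - 1 / l)
    total <- total + term
  }
  total
}

#' Effective Born radii (OBC-II)
#'
#' HCT pairwise descreening sums rescaled by the OBC tanh correction:
#' `1/R_i = 1/rho_t_i - tanh(a*Psi - b*Psi^2 + g*Psi^3) / rho_i` with
#' `Psi = rho_t_i * I_i`, offset 0.09 A and OBC-II constants
#' `a = 1, b = 0.8, g = 4.85`.  An isolated atom reduces to
#' `R = rho - offset`.
#'
#' @param xyz N x 3 coordinates (A).
#' @param gb_radius intrinsic radii (A).
#' @param screen HCT screening factors (default 1).
#' @param offset dielectric offset (A).
#' @param obc `c(alpha, beta, gamma)` tanh coefficients.
#' @return per-atom effective radii (A).
#' @export
effective_born_radii <- function(xyz, gb_radius, screen = rep(1, nrow(xyz)),
                                 offset = 0.09,
                                 obc = c(1.0, 0.8, 4.85)) {
  n <- nrow(xyz)
  rho_t <- gb_radius - offset
  if (any(rho_t <= 0)) stopf("GB radius must exceed the dielectric offset")
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    if (any(d[upper.tri(d)] < 1e-9)) stopf("overlapping identical centers")
  }
  vapply(seq_len(n), function(i) {
    if (n == 1) return(rho_t[i])
    js <- setdiff(seq_len(n), i)
    psi <- rho_t[i] * hct_integral(rho_t[i], screen[js] * rho_t[js], d[i, js])
    inv <- 1 / rho_t[i] -
      tanh(obc[1] * psi - obc[2] * psi^2 + obc[3] * psi^3) / gb_radius[i]
    1 / inv
  }, numeric(1))
}

#' Generalized-Born polar solvation energy
#'
#' `-1/2 (1/eps_in - 1/eps_solv) 332.0637 sum_{i,j} q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`, including the
#' `i = j` Born self terms.  No distance cutoff is applied: the long-range
#' screened cross terms are the physics of the model.
#'
#' @param xyz N x 3 coordinates (A).
#' @param charge per-atom charges (e).
#' @param born_radii effective radii from [effective_born_radii()].
#' @param eps_in,eps_solv interior and solvent dielectric constants.
#' @return energy in kcal/mol (<= 0 for `eps_solv > eps_in`).
#' @export
gb_polar_energy <- function(xyz, charge, born_radii, eps_in = 1,
                            eps_solv = 78.5) {
  n <- nrow(xyz)
  pref <- -0.5 * (1 / eps_in - 1 / eps_solv) * COULOMB_K
  total <- sum(charge^2 / born_radii)  # self terms (f_GB = R_i at r = 0)
  if (n > 1) {
    pairs <- pair_set(seq_len(n))
    r2 <- rowSums((xyz[pairs[, 1], , drop = FALSE] -
                   xyz[pairs[, 2], , drop = FALSE])^2)
    rr <- born_radii[pairs[, 1]] * born_radii[pairs[, 2]]
    fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
    total <- total + 2 * sum(charge[pairs[, 1]] * charge[pairs[, 2]] / fgb)
  }
  pref * total
}

#' LCPO solvent-accessible surface area
#'
#' Linear combination of pairwise overlaps: per atom,
#' `P1*S1 + P2*sum_j A_ij + P3*sum_{j,k} A_jk + P4*sum_j A_ij sum_k A_jk`
#' with `S1 = 4 pi R_i^2`, `A_ij` the buried-cap area of neighbour j on
#' sphere i, and all radii inflated by the probe radius.  Negative per-atom
#' contributions are clamped to zero.
#'
#' @param xyz N x 3 coordinates (A).
#' @param lcpo_radius atomic radii (A), probe excluded.
#' @param p1,p2,p3,p4 per-atom LCPO coefficients.
#' @param probe solvent probe radius (A).
#' @return list with `per_atom` (A^2) and `total` (A^2).
#' @export
lcpo_sasa <- function(xyz, lcpo_radius, p1, p2, p3, p4, probe = 1.4) {
  n <- nrow(xyz)
  rr <- lcpo_radius + probe
  s1 <- 4 * pi * rr^2
  if (n == 1) {
    per <- pmax(0, p1 * s1)
    return(list(per_atom = per, total = sum(per)))
  }
  d <- as.matrix(stats::dist(xyz))
  nb <- lapply(seq_len(n), function(i)
    which(d[i, ] < rr[i] + rr & seq_len(n) != i))
  aij <- function(i, j) {
    dd <- d[i, j]
    2 * pi * rr[i] * (rr[i] - dd / 2 - (rr[i]^2 - rr[j]^2) / (2 * dd))
  }
  per <- vapply(seq_len(n), function(i) {
    js <- nb[[i]]
    if (length(js) == 0) return(p1[i] * s1[i])
    sum_aij <- 0; sum_ajk <- 0; sum_prod <- 0
    for (j in js) {
      a_ij <- aij(i, j)
      sum_aij <- sum_aij + a_ij
      ks <- intersect(js, nb[[j]])
      ks <- ks[ks != j]
      a_jk_sum <- if (length(ks)) sum(vapply(ks, function(k) aij(j, k),
                                             numeric(1))) else 0
      sum_ajk <- sum_ajk + a_jk_sum
      sum_prod <- sum_prod + a_ij * a_jk_sum
    }
    p1[i] * s1[i] + p2[i] * sum_aij + p3[i] * sum_ajk + p4[i] * sum_prod
  }, numeric(1))
  per <- pmax(0, per)
  list(per_atom = per, total = sum(per))
}

#' Nonpolar solvation energy from total SASA
#'
#' Linear surface-tension model `gamma * SASA + b`.
#'
#' @param sasa total solvent-accessible surface area (A^2), >= 0.
#' @param gamma surface tension (kcal/mol/A^2).
#' @param b offset (kcal/mol).
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa, gamma = 0.005, b = 0) {
  if (sasa < 0) stopf("SASA must be nonnegative")
  gamma * sasa + b
}
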