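# Internal-coordinate atom placement and ideal peptide geometry.
#
# Bond lengths/angles are standard trans-peptide values; the Cbeta is placed
# with L-chirality, i.e. signed volume det[N-CA, C-CA, CB-CA] > 0 and torsion
# N-C-CA-CB = +122.6 degrees.

# ideal backbone geometry (Angstrom / degrees)
GEOM <- list(
  b_n_ca  = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23, b_ca_cb = 1.53,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_c_ca_cb = 110.1, t_n_c_ca_cb = 122.6,
  omega = 180.0)

PHI_PSI <- list(extended = c(phi = -140, psi = 135),
                helical  = c(phi = -57,  psi = -47))

# Place atom D given positions A, B, C so that |C-D| = bond,
# angle(B,C,D) = ang (deg) and torsion(A,B,C,D) = tors (deg).  NeRF scheme.
place_atom <- function(a, b, c, bond, ang, tors) {
  ang <- deg2rad(ang); tors <- deg2rad(tors)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tors),
          bond * sin(ang) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -atan2(y, x) * 180 / pi  # IUPAC sign convention
}

bond_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Idealized Cbeta from backbone N, CA, C (L-amino-acid chirality).
place_cbeta <- function(n, ca, c) {
  place_atom(n, c, ca, GEOM$b_ca_cb, GEOM$a_c_ca_cb, GEOM$t_n_c_ca_cb)
}

# sp2 carbonyl oxygen: in the CA-C-Nnext plane, anti to Nnext.
place_carbonyl_o <- function(ca, c, n_next) {
  dir <- -(unit(n_next - c) + unit(ca - c))
  c + GEOM$b_c_o * unit(dir)
}

# Build ideal backbone coordinates for `n_res` residues walking C-terminally
# from seed atoms (prevN, prevCA, prevC).  Returns list of per-residue lists
# with N, CA, C (no O; the caller places O once the next N is known).
walk_backbone_c <- function(prev_n, prev_ca, prev_c, n_res, phi, psi) {
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    n  <- place_atom(prev_n, prev_ca, prev_c, GEOM$b_c_n, GEOM$a_ca_c_n, psi)
    ca <- place_atom(prev_ca, prev_c, n, GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
    c  <- place_atom(prev_c, n, ca, GEOM$b_ca_c, GEOM$a_n_ca_c, phi)
    out[[i]] <- list(N = n, CA = ca, C = c)
    prev_n <- n; prev_ca <- ca; prev_c <- c
  }
  out
}

# Walk N-terminally from seed atoms (nextC, nextCA, nextN); returns residues
# ordered N->C (i.e. reversed build order).
walk_backbone_n <- function(next_c, next_ca, next_n, n_res, phi, psi) {
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    c  <- place_atom(next_c, next_ca, next_n, GEOM$b_c_n, GEOM$a_c_n_ca, phi)
    ca <- place_atom(next_ca, next_n, c, GEOM$b_ca_c, GEOM$a_ca_c_n, GEOM$omega)
    n  <- place_atom(next_n, c, ca, GEOM$b_n_ca, GEOM$a_n_ca_c, psi)
    out[[i]] <- list(N = n, CA = ca, C = c)
    next_c <- c; next_ca <- ca; next_n <- n
  }
  rev(out)
}
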