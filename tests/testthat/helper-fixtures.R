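# Shared fixtures: all inputs are generated in code.

# minimal hand-written PDB text: 2 chains, 4 residues (GLY has no CB)
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.005   1.419   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   1       2.010  -0.770   1.170  1.00  0.00           C",
    "ATOM      5  N   GLY A   2       1.210   2.459   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       1.650   3.850   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       0.480   4.820   0.000  1.00  0.00           C",
    "TER",
    "ATOM      8  N   LEU B  10      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      9  CA  LEU B  10      11.460   0.000   0.000  1.00  0.00           C",
    "ATOM     10  C   LEU B  10      12.005   1.419   0.000  1.00  0.00           C",
    "ATOM     11  N   SER B  11      11.210   2.459   0.000  1.00  0.00           N",
    "ATOM     12  CA  SER B  11      11.650   3.850   0.000  1.00  0.00           C",
    "ATOM     13  C   SER B  11      10.480   4.820   0.000  1.00  0.00           C",
    "END")
}

write_tiny_pdb <- function() {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(tiny_pdb_lines(), f)
  f
}

# the standard toy complex used across interface/GBSA tests:
# helical receptor (one Lys) + extended acidic partner at a 4 A gap
test_complex <- function(gap = 4, axis = c(0, 0, 1)) {
  rec <- build_toy_peptide("KLLALALLALAL", "helical", chain = "A",
                           start = 101)
  par <- build_toy_peptide("ELLALLA", "extended", chain = "B", start = 61)
  make_complex(rec, par, gap = gap, axis = axis, label = "test complex")
}

# two-residue salt-bridge system with explicit charged-group atoms
salt_bridge_structure <- function(d_no = 2.8) {
  mk <- ppistab:::make_atom_row
  at <- rbind(
    mk("CB", "C", "LYS", "A", 1, c(0, 0, 0)),
    mk("NZ", "N", "LYS", "A", 1, c(2.0, 0, 0)),
    mk("CB", "C", "GLU", "B", 1, c(2.0 + d_no + 2.0, 0, 0)),
    mk("OE1", "O", "GLU", "B", 1, c(2.0 + d_no, 0, 0)),
    mk("OE2", "O", "GLU", "B", 1, c(2.0 + d_no + 0.7, 1.0, 0)))
  ppistab:::new_structure(ppistab:::renumber_elenos(at))
}

# deterministic Shrake-Rupley SASA oracle (golden-spiral point set)
shrake_rupley_sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  rr <- radii + probe
  n <- nrow(xyz)
  i_seq <- seq_len(n_points) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i_seq / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i_seq
  sphere <- cbind(r * cos(th), r * sin(th), z)
  vapply(seq_len(n), function(i) {
    pts <- sweep(sphere * rr[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in setdiff(seq_len(n), i)) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      acc <- acc & d2 > rr[j]^2
    }
    4 * pi * rr[i]^2 * mean(acc)
  }, numeric(1))
}

# random small coordinate clouds with a minimum separation
random_cloud <- function(n, spread = 6, min_sep = 1.2) {
  repeat {
    m <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
    if (n == 1 || min(stats::dist(m)) > min_sep) return(m)
  }
}

rigid_transform <- function(m, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
  sweep(m %*% t(rot), 2, shift, `+`)
}
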