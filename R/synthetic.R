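# Seeded synthetic-data generators: ideal-geometry toy peptides, two-chain
# complexes at a prescribed gap, structure ensembles with planted
# orthonormal modes, bound (stationary jitter) and dissociating (rigid
# partner drift) trajectories, and closed-form charge/sphere systems for
# validating the GB/SASA energy terms.  Every generator is bit-reproducible
# under a fixed seed.

#' Build an ideal-geometry toy peptide
#'
#' Backbone (N, CA, C, O) plus an idealized C-beta for non-glycine
#' residues, in an extended (phi = -140, psi = 135) or helical
#' (phi = -57, psi = -47) conformation.
#'
#' @param sequence one-letter sequence (standard 20 codes).
#' @param conformation `"extended"` or `"helical"`.
#' @param chain chain identifier.
#' @param start first author residue number.
#' @return a `ppi_structure`.
#' @export
build_toy_peptide <- function(sequence, conformation = c("extended",
                                                         "helical"),
                              chain = "A", start = 1L) {
  conformation <- match.arg(conformation)
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) == 0) stopf("empty sequence")
  bad <- setdiff(seq1, names(aa_three))
  if (length(bad) > 0) stopf("invalid one-letter code(s): %s",
                             paste(unique(bad), collapse = ""))
  angles <- PHI_PSI[[conformation]]
  n1 <- c(0, 0, 0)
  ca1 <- c(GEOM$b_n_ca, 0, 0)
  ang <- deg2rad(GEOM$a_n_ca_c)
  c1 <- ca1 + GEOM$b_ca_c * c(-cos(ang), sin(ang), 0)
  bb <- c(list(list(N = n1, CA = ca1, C = c1)),
          if (length(seq1) > 1)
            walk_backbone_c(n1, ca1, c1, length(seq1) - 1,
                            angles["phi"], angles["psi"]))
  virt <- place_atom(bb[[length(seq1)]]$N, bb[[length(seq1)]]$CA,
                     bb[[length(seq1)]]$C, GEOM$b_c_n, GEOM$a_ca_c_n,
                     angles["psi"])
  next_n <- c(bb[-1], list(list(N = virt)))
  at <- do.call(rbind, lapply(seq_along(seq1), function(i) {
    res3 <- unname(aa_three[seq1[i]])
    b <- bb[[i]]
    rows <- list(
      make_atom_row("N", "N", res3, chain, start + i - 1L, b$N),
      make_atom_row("CA", "C", res3, chain, start + i - 1L, b$CA),
      make_atom_row("C", "C", res3, chain, start + i - 1L, b$C),
      make_atom_row("O", "O", res3, chain, start + i - 1L,
                    place_carbonyl_o(b$CA, b$C, next_n[[i]]$N)))
    if (res3 != "GLY")
      rows <- c(rows, list(make_atom_row("CB", "C", res3, chain,
                                         start + i - 1L,
                                         place_cbeta(b$N, b$CA, b$C))))
    do.call(rbind, rows)
  }))
  new_structure(renumber_elenos(at),
                model_id = sprintf("toy-%s", conformation))
}

#' Assemble a two-chain complex at a prescribed gap
#'
#' The partner is rigidly translated along `axis` until the minimum
#' inter-chain heavy-atom distance equals `gap` (within 0.01 A).
#'
#' @param receptor,partner `ppi_structure` objects (must use different
#'   chain identifiers).
#' @param gap target minimum heavy-atom distance (A).
#' @param axis translation direction (3-vector, normalised internally).
#' @param label label for the complex definition.
#' @return list with `structure` (a `ppi_structure`) and `cdef`
#'   (a `complex_def`).
#' @export
make_complex <- function(receptor, partner, gap = 4.0, axis = c(1, 0, 0),
                         label = "toy complex") {
  axis <- unit(axis)
  if (length(intersect(receptor$atom$chain, partner$atom$chain)) > 0)
    stopf("receptor and partner must use different chain identifiers")
  rxyz <- as.matrix(receptor$atom[is_heavy_atom(receptor$atom),
                                  c("x", "y", "z")])
  pxyz0 <- as.matrix(partner$atom[is_heavy_atom(partner$atom),
                                  c("x", "y", "z")])
  gap_at <- function(t) {
    pair_min_dist(rxyz, sweep(pxyz0, 2, t * axis, `+`)) - gap
  }
  # start near centroid overlap (gap function negative) and walk outward
  # along +axis until positive, then root-find on that increasing arm
  diam <- max(stats::dist(rbind(rxyz, pxyz0))) + gap + 1
  t_c <- sum((colMeans(rxyz) - colMeans(pxyz0)) * axis)
  lo <- t_c
  if (gap_at(lo) > 0) {
    grid <- seq(t_c - diam, t_c + diam, length.out = 401)
    vals <- vapply(grid, gap_at, numeric(1))
    if (min(vals) > 0)
      stopf("cannot reach the target gap by translation along this axis")
    lo <- grid[which.min(vals)]
  }
  hi <- lo
  while (gap_at(hi) <= 0) hi <- hi + max(1, diam / 8)
  t_star <- stats::uniroot(gap_at, c(lo, hi), tol = 1e-8)$root
  pat <- partner$atom
  pat$x <- pat$x + t_star * axis[1]
  pat$y <- pat$y + t_star * axis[2]
  pat$z <- pat$z + t_star * axis[3]
  combined <- new_structure(renumber_elenos(rbind(receptor$atom, pat)),
                            model_id = "toy-complex")
  rec_sel <- sprintf("%s:%d-%d", receptor$atom$chain[1],
                     min(receptor$atom$resno), max(receptor$atom$resno))
  par_sel <- sprintf("%s:%d-%d", pat$chain[1], min(pat$resno),
                     max(pat$resno))
  list(structure = combined,
       cdef = complex_definition(rec_sel, par_sel, label, combined))
}

#' Structure ensemble with planted orthonormal displacement modes
#'
#' Member k is the base structure displaced by
#' `sum_j a_kj * mode_j` with `a_kj ~ Normal(0, variance_j)`; each
#' residue moves rigidly by its C-alpha mode component, so a C-alpha PCA
#' sees exactly the planted covariance structure.  Optionally each member
#' receives a random rigid motion (which coordinate PCA must undo by
#' superposition).
#'
#' @param base a `ppi_structure`.
#' @param modes matrix (3 * n_residues) x m; columns must be orthonormal
#'   over the C-alpha coordinate space.
#' @param variances per-mode variances (A^2), > 0.
#' @param n ensemble size.
#' @param seed RNG seed.
#' @param rigid apply a random rigid motion to each member?
#' @return list of `n` `ppi_structure` objects.
#' @export
ensemble_with_planted_modes <- function(base, modes, variances, n, seed,
                                        rigid = FALSE) {
  modes <- as.matrix(modes)
  m <- ncol(modes)
  if (length(variances) != m || any(variances <= 0))
    stopf("need one positive variance per mode")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(m))) > 1e-6) stopf("modes are not orthonormal")
  res_rows <- residue_split(base$atom)
  if (nrow(modes) != 3L * length(res_rows))
    stopf("mode length (%d) does not match 3 x residue count (%d)",
          nrow(modes), 3L * length(res_rows))
  with_seed(seed, {
    coeff <- matrix(stats::rnorm(n * m, sd = rep(sqrt(variances),
                                                 each = n)), n, m)
    lapply(seq_len(n), function(k) {
      disp <- xyz_to_mat(as.numeric(modes %*% coeff[k, ]))
      at <- base$atom
      for (i in seq_along(res_rows)) {
        r <- res_rows[[i]]
        at$x[r] <- at$x[r] + disp[i, 1]
        at$y[r] <- at$y[r] + disp[i, 2]
        at$z[r] <- at$z[r] + disp[i, 3]
      }
      s <- new_structure(at, model_id = sprintf("member%d", k))
      if (rigid) s <- random_rigid_motion(s)
      s
    })
  })
}

#' Orthonormal internal modes from raw displacement vectors
#'
#' Projects raw C-alpha displacement vectors onto the complement of the
#' rigid-body subspace (3 translations + 3 rotations about the centroid)
#' and orthonormalizes them.  Superposition removes rigid motion before
#' PCA, so only internal modes are recoverable; planting raw modes with a
#' rigid component would silently lose that component.
#'
#' @param base a `ppi_structure` (supplies the C-alpha geometry).
#' @param raw matrix (3 * n_residues) x m of raw displacement vectors.
#' @return matrix of the same shape with orthonormal, rigid-free columns.
#' @export
orthonormal_modes <- function(base, raw) {
  raw <- as.matrix(raw)
  ca <- base$atom[base$atom$elety == "CA" & is_heavy_atom(base$atom), ,
                  drop = FALSE]
  x <- sweep(as.matrix(ca[, c("x", "y", "z")]), 2,
             colMeans(as.matrix(ca[, c("x", "y", "z")])))
  n <- nrow(x)
  if (nrow(raw) != 3L * n)
    stopf("raw mode length (%d) does not match 3 x CA count (%d)",
          nrow(raw), 3L * n)
  rigid <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    mat_to_xyz(cbind(0, -x[, 3], x[, 2])),
    mat_to_xyz(cbind(x[, 3], 0, -x[, 1])),
    mat_to_xyz(cbind(-x[, 2], x[, 1], 0)))
  qb <- qr.Q(qr(rigid))
  proj <- raw - qb %*% crossprod(qb, raw)
  out <- qr.Q(qr(proj))[, seq_len(ncol(raw)), drop = FALSE]
  # fix column signs for reproducibility
  for (j in seq_len(ncol(out))) {
    i <- which.max(abs(out[, j]))
    if (out[i, j] < 0) out[, j] <- -out[, j]
  }
  out
}

random_rigid_motion <- function(s) {
  q <- stats::rnorm(4); q <- q / vnorm(q)
  rot <- quat_to_rot(q)
  tr <- stats::rnorm(3, sd = 5)
  xyz <- xyz_to_mat(structure_xyz(s)) %*% t(rot)
  set_structure_xyz(s, mat_to_xyz(sweep(xyz, 2, tr, `+`)))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Bound-complex trajectory: stationary Gaussian jitter
#'
#' Each frame is the input complex plus i.i.d. Gaussian displacement of
#' standard deviation `sigma` per atom coordinate.  Emulates a complex that
#' stays bound: no net drift, so separation maps average to zero.
#'
#' @param complex a `ppi_structure` (e.g. from [make_complex()]).
#' @param sigma per-coordinate jitter SD (A), >= 0.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `ppi_trajectory`.
#' @export
trajectory_bound <- function(complex, sigma, n_frames, seed) {
  if (sigma < 0) stopf("sigma must be nonnegative")
  base <- structure_xyz(complex)
  xyz <- with_seed(seed, {
    t(vapply(seq_len(n_frames), function(k)
      base + stats::rnorm(length(base), sd = sigma),
      numeric(length(base))))
  })
  new_trajectory(complex, xyz)
}

#' Dissociating trajectory: rigid partner drift plus jitter
#'
#' At frame k (1-based) the partner chain is rigidly translated by
#' `(k - 1) * drift`; optional Gaussian jitter `sigma` is added to all
#' atoms.  Emulates progressive dissociation of the partner.
#'
#' @param complex a `ppi_structure`.
#' @param partner_chain chain identifier of the drifting partner.
#' @param drift 3-vector translation per frame (A/frame), nonzero.
#' @param sigma per-coordinate jitter SD (A).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `ppi_trajectory`.
#' @export
trajectory_dissociating <- function(complex, partner_chain, drift, sigma,
                                    n_frames, seed) {
  if (vnorm(drift) == 0) stopf("drift vector must be nonzero")
  if (!partner_chain %in% complex$atom$chain)
    stopf("unknown chain identifier '%s'", partner_chain)
  base <- structure_xyz(complex)
  pidx <- which(complex$atom$chain == partner_chain)
  pcols <- atom_xyz_cols(pidx)
  shift_tpl <- rep(drift, length(pidx))
  xyz <- with_seed(seed, {
    t(vapply(seq_len(n_frames), function(k) {
      v <- base
      v[pcols] <- v[pcols] + (k - 1) * shift_tpl
      if (sigma > 0) v <- v + stats::rnorm(length(v), sd = sigma)
      v
    }, numeric(length(base))))
  })
  new_trajectory(complex, xyz)
}

#' Closed-form toy charge/sphere systems for energy-term validation
#'
#' Available kinds: `"born_ion"` (one ion with a prescribed *effective*
#' Born radius `R`), `"ion_pair"` (charges `q1`, `q2` at distance `r`),
#' `"lj_pair"` (two identical LJ atoms at distance `r`), `"sphere"` (one
#' uncharged sphere of radius `radius`), `"sphere_pair"` (two spheres at
#' distance `r`) and `"cage"` (a central atom tightly enclosed by 26
#' neighbours at spacing `a`).
#'
#' @param kind system kind (see Details).
#' @param ... kind-specific parameters with sensible defaults.
#' @return list with `xyz` (N x 3) and `params` (an `atom_params` table).
#' @export
toy_charge_system <- function(kind = c("born_ion", "ion_pair", "lj_pair",
                                       "sphere", "sphere_pair", "cage"),
                              ...) {
  kind <- match.arg(kind)
  args <- list(...)
  mk <- function(xyz, charge = 0, gb_radius = 2.09, lcpo_radius = 1.7,
                 eps = 0.1, rmin = 1.7) {
    n <- nrow(xyz)
    rep_n <- function(v) rep_len(v, n)
    params <- validate_params(data.frame(
      chain = "X", resno = seq_len(n), atomname = "DU",
      charge = rep_n(charge), eps = rep_n(eps), rmin = rep_n(rmin),
      gb_radius = rep_n(gb_radius), screen = 1,
      lcpo_p1 = 1, lcpo_p2 = -1, lcpo_p3 = 0, lcpo_p4 = 0,
      lcpo_radius = rep_n(lcpo_radius), stringsAsFactors = FALSE))
    list(xyz = xyz, params = params)
  }
  switch(kind,
    born_ion = {
      q <- args$q %||% 1; R <- args$R %||% 2.0
      mk(matrix(0, 1, 3), charge = q, gb_radius = R + 0.09)
    },
    ion_pair = {
      r <- args$r %||% 10; q1 <- args$q1 %||% 1; q2 <- args$q2 %||% -1
      R <- args$R %||% 2.0
      mk(rbind(c(0, 0, 0), c(r, 0, 0)), charge = c(q1, q2),
         gb_radius = R + 0.09)
    },
    lj_pair = {
      r <- args$r %||% 3.5; eps <- args$eps %||% 0.2
      rmin_half <- args$rmin_half %||% 1.7
      mk(rbind(c(0, 0, 0), c(r, 0, 0)), eps = eps, rmin = rmin_half)
    },
    sphere = {
      radius <- args$radius %||% 1.7
      mk(matrix(0, 1, 3), lcpo_radius = radius)
    },
    sphere_pair = {
      r <- args$r %||% 2.5; radius <- args$radius %||% 1.7
      mk(rbind(c(0, 0, 0), c(r, 0, 0)), lcpo_radius = radius)
    },
    cage = {
      a <- args$a %||% 1.8
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * a
      mk(rbind(c(0, 0, 0), g[rowSums(abs(g)) > 0, ]))
    })
}
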