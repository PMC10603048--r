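test_that("Coulomb energies match the closed form and a pair-loop oracle", {
  xy <- rbind(c(0, 0, 0), c(3.320637, 0, 0))
  expect_equal(coulomb_energy(xy, c(1, -1), cutoff = Inf), -100,
               tolerance = 1e-9)
  expect_equal(coulomb_energy(xy, c(0, 0), cutoff = Inf), 0)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "coincident")

  withr::with_seed(21, {
    m <- random_cloud(5)
    q <- runif(5, -1, 1)
    oracle <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      r <- sqrt(sum((m[i, ] - m[j, ])^2))
      if (r <= 18) oracle <- oracle + 332.0637 * q[i] * q[j] / r
    }
    expect_equal(coulomb_energy(m, q), oracle, tolerance = 1e-9)
  })
})

test_that("LJ energies hit the analytic minimum and zero crossing", {
  sys <- toy_charge_system("lj_pair", r = 3.4, eps = 0.2, rmin_half = 1.7)
  expect_equal(lj_energy(sys$xyz, sys$params$eps, sys$params$rmin), -0.2,
               tolerance = 1e-9)
  sys0 <- toy_charge_system("lj_pair", r = 3.4 / 2^(1 / 6), eps = 0.2,
                            rmin_half = 1.7)
  expect_equal(lj_energy(sys0$xyz, sys0$params$eps, sys0$params$rmin), 0,
               tolerance = 1e-9)
  expect_error(lj_energy(sys$xyz, sys$params$eps, c(-1, 1)), "nonpositive")

  withr::with_seed(22, {
    m <- random_cloud(5, min_sep = 3)
    eps <- runif(5, 0.05, 0.3); rmin <- runif(5, 1.5, 2.1)
    oracle <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      r <- sqrt(sum((m[i, ] - m[j, ])^2))
      if (r <= 18) {
        rm_ij <- rmin[i] + rmin[j]; e_ij <- sqrt(eps[i] * eps[j])
        oracle <- oracle + e_ij * ((rm_ij / r)^12 - 2 * (rm_ij / r)^6)
      }
    }
    expect_equal(lj_energy(m, eps, rmin), oracle, tolerance = 1e-9)
  })
})

test_that("effective Born radii obey the isolated and far limits", {
  sys <- toy_charge_system("born_ion", R = 2.0)
  expect_equal(effective_born_radii(sys$xyz, sys$params$gb_radius,
                                    sys$params$screen), 2.0,
               tolerance = 1e-9)
  far <- toy_charge_system("ion_pair", r = 500, R = 2.0)
  rr <- effective_born_radii(far$xyz, far$params$gb_radius,
                             far$params$screen)
  expect_equal(rr, c(2.0, 2.0), tolerance = 1e-6)
  expect_error(effective_born_radii(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    c(1.5, 1.5)), "overlapping")
})

test_that("Born radii match a numerical descreening integral", {
  # independent oracle: Monte-Carlo evaluation of the 1/r^4 descreening
  # volume integral over each neighbour sphere, then the same OBC rescale
  xyz <- rbind(c(0, 0, 0), c(3.2, 0.5, -0.2), c(-1.5, 2.0, 1.0))
  rho <- c(1.7, 1.55, 1.5)
  r_pkg <- effective_born_radii(xyz, rho)
  rho_t <- rho - 0.09
  withr::with_seed(99, {
    for (i in 1:3) {
      total <- 0
      for (j in setdiff(1:3, i)) {
        s <- rho_t[j]
        pts <- matrix(runif(3 * 2e5, -s, s), ncol = 3)
        inside <- rowSums(pts^2) < s^2
        pts <- sweep(pts[inside, , drop = FALSE], 2, xyz[j, ], `+`)
        r2 <- rowSums(sweep(pts, 2, xyz[i, ])^2)
        integrand <- ifelse(r2 > rho_t[i]^2, 1 / r2^2, 0)
        total <- total + mean(integrand) * (2 * s)^3 * mean(inside) /
          (4 * pi)
      }
      psi <- rho_t[i] * total
      r_num <- 1 / (1 / rho_t[i] -
                    tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / rho[i])
      expect_equal(r_pkg[i], r_num, tolerance = 2e-3)
    }
  })
})

test_that("GB polar energy reproduces the Born ion and screened-Coulomb limits", {
  sys <- toy_charge_system("born_ion", q = 1, R = 2.0)
  re <- effective_born_radii(sys$xyz, sys$params$gb_radius)
  born <- -0.5 * (1 - 1 / 78.5) * 332.0637 / 2.0
  expect_equal(gb_polar_energy(sys$xyz, sys$params$charge, re), born,
               tolerance = 1e-6)

  expect_equal(gb_polar_energy(sys$xyz, 0, re), 0)
  expect_lt(gb_polar_energy(sys$xyz, sys$params$charge, re), 0)

  pair <- toy_charge_system("ion_pair", r = 50, q1 = 1, q2 = -1, R = 2.0)
  rp <- effective_born_radii(pair$xyz, pair$params$gb_radius)
  e_pair <- gb_polar_energy(pair$xyz, pair$params$charge, rp)
  cross <- e_pair -
    gb_polar_energy(pair$xyz[1, , drop = FALSE], 1, rp[1]) -
    gb_polar_energy(pair$xyz[2, , drop = FALSE], -1, rp[2])
  limit <- -(1 - 1 / 78.5) * 332.0637 * (1 * -1) / 50
  expect_lt(abs(cross - limit) / abs(limit), 0.001)
})

test_that("GB cross terms approach screened Coulomb monotonically with distance", {
  prev <- -Inf
  for (r in c(5, 10, 20, 40, 80)) {
    pair <- toy_charge_system("ion_pair", r = r, q1 = 1, q2 = -1, R = 2.0)
    rp <- effective_born_radii(pair$xyz, pair$params$gb_radius)
    cross <- gb_polar_energy(pair$xyz, pair$params$charge, rp) -
      gb_polar_energy(pair$xyz[1, , drop = FALSE], 1, rp[1]) -
      gb_polar_energy(pair$xyz[2, , drop = FALSE], -1, rp[2])
    ratio <- cross / (-(1 - 1 / 78.5) * 332.0637 * (-1) / r)
    expect_gt(ratio, 0)
    expect_lt(abs(ratio - 1), abs(prev - 1) + 1e-12)
    prev <- ratio
  }
})

test_that("LCPO SASA matches sphere closed forms and a Shrake-Rupley oracle", {
  sys <- toy_charge_system("sphere", radius = 1.7)
  out <- lcpo_sasa(sys$xyz, sys$params$lcpo_radius, 1, -1, 0, 0)
  expect_equal(out$total, 4 * pi * 3.1^2, tolerance = 1e-9)

  cage <- toy_charge_system("cage", a = 1.8)
  n <- nrow(cage$xyz)
  caged <- lcpo_sasa(cage$xyz, cage$params$lcpo_radius, rep(1, n),
                     rep(-1, n), rep(0, n), rep(0, n))
  expect_lt(caged$per_atom[1], 1e-9)

  for (r in c(2.0, 2.8, 4.5)) {
    sp <- toy_charge_system("sphere_pair", r = r, radius = 1.7)
    v <- lcpo_sasa(sp$xyz, sp$params$lcpo_radius, rep(1, 2), rep(-1, 2),
                   rep(0, 2), rep(0, 2))
    sr <- shrake_rupley_sasa(sp$xyz, sp$params$lcpo_radius)
    expect_lt(max(abs(v$per_atom - sr) / sr), 0.10)
  }
})

test_that("nonpolar energy is linear in surface area", {
  expect_equal(nonpolar_energy(1000), 5.0)
  expect_equal(nonpolar_energy(0), 0)
  expect_equal(nonpolar_energy(1000, gamma = 0.0072), 7.2)
  expect_error(nonpolar_energy(-1), "nonnegative")
})

test_that("binding enthalpy composes per the thermodynamic cycle", {
  # separated uncharged chains: every term vanishes
  rec <- build_toy_peptide("LALA", "extended", chain = "A")
  par <- build_toy_peptide("ALAL", "extended", chain = "B")
  cx <- make_complex(rec, par, gap = 60)
  be <- binding_energy(cx$structure, cx$cdef, toy_params(cx$structure),
                       cutoff = 18)
  expect_equal(be$total, 0, tolerance = 1e-6)

  # toy salt-bridge complex: equals hand composition from independently
  # scored species, and is attractive
  s <- salt_bridge_structure(d_no = 2.8)
  cd <- complex_definition("A:1-1", "B:1-1", "salt bridge", s)
  p <- toy_params(s)
  be2 <- binding_energy(s, cd, p, cutoff = Inf)
  expect_lt(be2$total, 0)
  expect_equal(be2$total,
               be2$e_elec + be2$e_vdw + be2$g_polar + be2$g_nonpolar,
               tolerance = 1e-9)

  # component-wise recomposition oracle from scratch
  at <- s$atom
  xyz <- ppistab:::xyz_to_mat(ppistab:::structure_xyz(s))
  pa <- ppistab:::align_params(s, p)
  idx_a <- which(at$chain == "A"); idx_b <- which(at$chain == "B")
  g_of <- function(idx) {
    sub <- xyz[idx, , drop = FALSE]
    rr <- effective_born_radii(sub, pa$gb_radius[idx], pa$screen[idx])
    gp <- gb_polar_energy(sub, pa$charge[idx], rr)
    sasa <- lcpo_sasa(sub, pa$lcpo_radius[idx], pa$lcpo_p1[idx],
                      pa$lcpo_p2[idx], pa$lcpo_p3[idx],
                      pa$lcpo_p4[idx])$total
    gp + nonpolar_energy(sasa)
  }
  inter <- coulomb_energy(xyz, pa$charge, idx_a, idx_b, cutoff = Inf) +
    lj_energy(xyz, pa$eps, pa$rmin, idx_a, idx_b, cutoff = Inf)
  oracle <- inter + g_of(c(idx_a, idx_b)) - g_of(idx_a) - g_of(idx_b)
  expect_equal(be2$total, oracle, tolerance = 1e-9)
})

test_that("all energy terms are rigid-motion invariant", {
  s <- salt_bridge_structure(d_no = 3.0)
  cd <- complex_definition("A:1-1", "B:1-1", "sb", s)
  p <- toy_params(s)
  be0 <- binding_energy(s, cd, p, cutoff = Inf)
  withr::with_seed(31, {
    for (k in 1:3) {
      m <- rigid_transform(
        ppistab:::xyz_to_mat(ppistab:::structure_xyz(s)),
        angle = runif(1, 0, pi), axis = rnorm(3), shift = rnorm(3, sd = 8))
      s2 <- ppistab:::set_structure_xyz(s, ppistab:::mat_to_xyz(m))
      be1 <- binding_energy(s2, cd, p, cutoff = Inf)
      for (f in c("e_elec", "e_vdw", "g_polar", "g_nonpolar", "total"))
        expect_equal(be1[[f]], be0[[f]], tolerance = 1e-6)
    }
  })
})

test_that("pose selection spaces frames evenly over the last half", {
  expect_equal(ppistab:::pose_frames(100, 5), c(51, 63, 75, 87, 99))
  expect_equal(ppistab:::pose_frames(10, 5), c(6, 7, 8, 9, 10))
  expect_error(ppistab:::pose_frames(9, 5), "too few")
})

test_that("multi-pose scores recompose from per-pose binding energies", {
  cx <- test_complex()
  params <- toy_params(cx$structure)

  # constant trajectory -> SD exactly 0
  tr0 <- trajectory_bound(cx$structure, 0, 20, seed = 1)
  bs0 <- multi_pose_score(tr0, cx$cdef, params, n_poses = 5)
  expect_equal(bs0$sd, 0)

  tr <- trajectory_bound(cx$structure, 0.15, 20, seed = 6)
  bs <- multi_pose_score(tr, cx$cdef, params, n_poses = 5)
  expect_equal(bs$frames, c(11, 13, 15, 17, 19))
  per <- vapply(bs$frames, function(f)
    binding_energy(ppistab:::frame_structure(tr, f), cx$cdef,
                   params)$total * 4.184, numeric(1))
  expect_equal(bs$per_pose, per, tolerance = 1e-9)
  expect_equal(bs$mean, mean(per), tolerance = 1e-9)
  expect_equal(bs$sd, sd(per), tolerance = 1e-9)
  expect_equal(bs$ligand_efficiency,
               ligand_efficiency(mean(per), bs$n_heavy_atoms))

  # rigid-body relaxation must not raise the intermolecular energy
  bsr <- multi_pose_score(tr, cx$cdef, params, n_poses = 2, relax = TRUE)
  expect_true(all(is.finite(bsr$per_pose)))
})

test_that("ligand efficiency divides by heavy atoms with half-away rounding", {
  expect_equal(ligand_efficiency(-130.94, 300), -0.44)
  expect_equal(ligand_efficiency(-48.06, 232), -0.21)
  expect_equal(ligand_efficiency(0, 100), 0.00)
  expect_equal(ligand_efficiency(-0.125 * 200, 200), -0.13)  # half away
  expect_error(ligand_efficiency(-50, 0), "positive")
})

test_that("parameter tables round-trip through the text format", {
  cx <- test_complex()
  p <- toy_params(cx$structure)
  f <- withr::local_tempfile(fileext = ".tbl")
  write.table(p, f, row.names = FALSE, quote = FALSE)
  p2 <- read_atom_params(f)
  expect_equal(p2$charge, p$charge)
  expect_equal(p2$gb_radius, p$gb_radius)
  be1 <- binding_energy(cx$structure, cx$cdef, p)
  be2 <- binding_energy(cx$structure, cx$cdef, p2)
  expect_equal(be1$total, be2$total, tolerance = 1e-12)

  # missing parameters are caught
  p3 <- p[-1, ]
  expect_error(binding_energy(cx$structure, cx$cdef, p3), "missing param")
})
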