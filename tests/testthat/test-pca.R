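test_that("Kabsch superposition recovers rigid motions exactly", {
  withr::with_seed(3, {
    m <- matrix(rnorm(30), 10, 3)
    same <- kabsch_superpose(m, m)
    expect_equal(same$rmsd, 0, tolerance = 1e-10)
    expect_equal(same$rotation, diag(3), tolerance = 1e-8)

    m2 <- rigid_transform(m, angle = pi / 2)
    fit <- kabsch_superpose(m2, m)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  })
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "mismatch")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "3 points")
})

test_that("Kabsch RMSD of a mirrored set matches a rotation-grid search", {
  # mirror image cannot be superposed by a proper rotation; the Kabsch
  # minimum must match an exhaustive search over fine Euler-angle grids
  pts <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2.1, 0), c(0.3, 0.4, 1.8))
  mirr <- pts %*% diag(c(1, 1, -1))
  fit <- kabsch_superpose(mirr, pts)

  grid_rmsd <- function(mob, ref, n_coarse = 24) {
    a <- sweep(mob, 2, colMeans(mob)); b <- sweep(ref, 2, colMeans(ref))
    rot_z <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                                  0, 0, 1), 3, 3, byrow = TRUE)
    rot_y <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                                  -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    eval_r <- function(ang) {
      r <- rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])
      sqrt(mean(rowSums((a %*% t(r) - b)^2)))
    }
    best <- Inf; best_ang <- NULL
    th <- seq(0, 2 * pi, length.out = n_coarse + 1)[-1]
    ph <- seq(0, pi, length.out = n_coarse %/% 2)
    for (t1 in th) for (t2 in ph) for (t3 in th) {
      v <- eval_r(c(t1, t2, t3))
      if (v < best) { best <- v; best_ang <- c(t1, t2, t3) }
    }
    # local polish around the best coarse cell
    opt <- stats::optim(best_ang, eval_r, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    min(best, opt$value)
  }
  expect_equal(fit$rmsd, grid_rmsd(mirr, pts), tolerance = 1e-3)
})

test_that("pairwise RMSD matrices agree with per-pair recomputation", {
  cx <- test_complex()
  tr <- trajectory_bound(cx$structure, 0.4, 4, seed = 8)
  m <- pairwise_rmsd_matrix(tr)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(diag(m), rep(0, 4))

  idx <- which(tr$topology$atom$elety == "CA" &
               ppistab:::is_heavy_atom(tr$topology$atom))
  cols <- ppistab:::atom_xyz_cols(idx)
  for (i in 1:3) for (j in (i + 1):4) {
    ora <- kabsch_superpose(ppistab:::xyz_to_mat(tr$xyz[i, cols]),
                            ppistab:::xyz_to_mat(tr$xyz[j, cols]))$rmsd
    expect_equal(m[i, j], ora, tolerance = 1e-12)
  }

  # duplicates give identically zero entries; 1-frame gives 1x1 zero
  tr0 <- trajectory_bound(cx$structure, 0, 3, seed = 1)
  expect_lt(max(abs(pairwise_rmsd_matrix(tr0))), 1e-9)
  tr1 <- trajectory_bound(cx$structure, 0.2, 1, seed = 1)
  expect_equal(pairwise_rmsd_matrix(tr1), matrix(0, 1, 1))
})

test_that("common cores intersect residues and honour exclusions", {
  full <- build_toy_peptide(paste(rep("A", 50), collapse = ""), "extended")
  gap <- full
  gap$atom <- gap$atom[!(gap$atom$resno %in% 20:25), ]
  core <- common_core(list(full, gap))
  expect_setequal(core$resno, c(1:19, 26:50))

  core2 <- common_core(list(full, gap), exclude = "A:30-40")
  expect_setequal(core2$resno, c(1:19, 26:29, 41:50))

  other <- build_toy_peptide("AAAA", "extended", chain = "B")
  expect_error(common_core(list(full, other)), "empty common core")
})

test_that("coordinate PCA recovers planted variance structure", {
  pep <- build_toy_peptide(paste(rep("A", 20), collapse = ""), "extended")
  raw <- matrix(0, 60, 2)
  raw[3 * 7 - 2, 1] <- 1   # residue 7, x
  raw[3 * 13 - 1, 2] <- 1  # residue 13, y
  modes <- orthonormal_modes(pep, raw)
  ens <- ensemble_with_planted_modes(pep, modes, c(9, 1), 500, seed = 42)
  pc <- coordinate_pca(ens)
  expect_lt(abs(pc$var_fractions[1] - 0.9), 0.03)
  expect_lt(abs(pc$var_fractions[2] - 0.1), 0.03)
  expect_equal(sum(pc$var_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # loadings orthonormal
  expect_lt(max(abs(crossprod(pc$loadings) -
                    diag(length(pc$eigenvalues)))), 1e-6)

  # independent oracle: sample-covariance eigendecomposition of the
  # superposed coordinates
  xc <- sweep(pc$xyz_fitted, 2, colMeans(pc$xyz_fitted))
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(pc$eigenvalues[1:2], ev[1:2], tolerance = 1e-8)

  expect_error(coordinate_pca(rep(list(pep), 5)), "zero variance")
})

test_that("coordinate PCA agrees with an independent ensemble-PCA tool", {
  pep <- build_toy_peptide(paste(rep("G", 12), collapse = ""), "helical")
  raw <- matrix(0, 36, 2)
  raw[4, 1] <- 1; raw[20, 2] <- 1
  modes <- orthonormal_modes(pep, raw)
  ens <- ensemble_with_planted_modes(pep, modes, c(4, 1), 60, seed = 9)
  pc <- coordinate_pca(ens)
  # bio3d as independent cross-check on the same fitted coordinates
  b3d <- bio3d::pca.xyz(pc$xyz_fitted)
  expect_equal(pc$var_fractions[1:3],
               (b3d$sdev^2 / sum(b3d$sdev^2))[1:3], tolerance = 1e-6)
})

test_that("rigidly moving the whole ensemble leaves the spectrum unchanged", {
  pep <- build_toy_peptide(paste(rep("A", 15), collapse = ""), "extended")
  raw <- matrix(0, 45, 1); raw[10, 1] <- 1
  modes <- orthonormal_modes(pep, raw)
  ens <- ensemble_with_planted_modes(pep, modes, 2, 40, seed = 4)
  pc0 <- coordinate_pca(ens)
  moved <- lapply(ens, function(s) {
    xyz <- rigid_transform(ppistab:::xyz_to_mat(
      ppistab:::structure_xyz(s)), angle = 1.1, axis = c(1, 2, 0.5))
    ppistab:::set_structure_xyz(s, ppistab:::mat_to_xyz(xyz))
  })
  pc1 <- coordinate_pca(moved)
  expect_equal(pc0$eigenvalues, pc1$eigenvalues, tolerance = 1e-6)
})

test_that("fluctuation profiles reduce to RMSF and grow monotonically in k", {
  pep <- build_toy_peptide(paste(rep("A", 18), collapse = ""), "extended")
  raw <- matrix(0, 54, 3)
  raw[3 * 7 - 2, 1] <- 1; raw[3 * 12 - 1, 2] <- 1; raw[3 * 3, 3] <- 1
  modes <- orthonormal_modes(pep, raw)
  ens <- ensemble_with_planted_modes(pep, modes, c(4, 2, 1), 200, seed = 12)
  pc <- coordinate_pca(ens)
  k_all <- length(pc$eigenvalues)

  prof_all <- fluctuation_profile(pc, k_all)$fluctuation
  xc <- sweep(pc$xyz_fitted, 2, colMeans(pc$xyz_fitted))
  rmsf <- sqrt(colSums(matrix(colSums(xc^2) / (nrow(xc) - 1), nrow = 3)))
  expect_equal(prof_all, rmsf, tolerance = 1e-6)

  prev <- rep(0, 18)
  for (k in 1:k_all) {
    cur <- fluctuation_profile(pc, k)$fluctuation
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
  # single planted dominant mode peaks at the planted residue
  expect_equal(which.max(fluctuation_profile(pc, 1)$fluctuation), 7)
  expect_error(fluctuation_profile(pc, 0), "must be in")
  expect_error(fluctuation_profile(pc, k_all + 1), "must be in")
})
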