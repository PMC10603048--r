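# Ensemble superposition, pairwise RMSD maps and coordinate PCA
# ("essential dynamics" over C-alpha coordinates).

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` (equal-size N x 3 matrices, N >= 3).
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @return list with `rotation` (3 x 3, det +1), `translation`, `rmsd`, and
#'   `coords` (the transformed mobile coordinates).  The fit is
#'   `coords = sweep(mobile, 2, cm_mob) %*% rotation + cm_ref`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stopf("point-count mismatch: %d vs %d", nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3) stopf("need at least 3 points to superpose")
  cm_m <- colMeans(mobile); cm_r <- colMeans(reference)
  a <- sweep(mobile, 2, cm_m); b <- sweep(reference, 2, cm_r)
  if (max(abs(a)) < 1e-9 || max(abs(b)) < 1e-9)
    stopf("degenerate point spread")
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot,
       translation = as.numeric(cm_r - cm_m %*% rot),
       rmsd = rmsd,
       coords = sweep(fitted, 2, cm_r, `+`))
}

#' Frame-vs-frame RMSD matrix of a trajectory
#'
#' Each entry is the least-squares RMSD after independent pairwise
#' superposition of the selected atoms (default: C-alpha).
#'
#' @param trajectory a `ppi_trajectory`.
#' @param selection selection string(s); default all chains' C-alphas.
#' @param atom_names atom names used for the fit.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(trajectory, selection = NULL,
                                 atom_names = "CA") {
  topo <- trajectory$topology
  segs <- if (is.null(selection)) {
    parse_selection(unique(topo$atom$chain), topo)
  } else parse_selection(selection, topo)
  idx <- selection_indices(topo, segs, atom_names = atom_names)
  if (length(idx) == 0) stopf("empty selection")
  cols <- atom_xyz_cols(idx)
  nf <- n_frames(trajectory)
  m <- matrix(0, nf, nf)
  coords <- lapply(seq_len(nf), function(i)
    xyz_to_mat(trajectory$xyz[i, cols]))
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
      m[i, j] <- r; m[j, i] <- r
    }
  }
  m
}

atom_xyz_cols <- function(idx) as.numeric(t(outer((idx - 1L) * 3L, 1:3, `+`)))

#' Residues with a C-alpha present in every ensemble member
#'
#' Intersects residue identities (chain, author number, insertion code)
#' across all structures, then removes any excluded ranges (e.g. a mobile
#' activation loop that is often unresolved in crystal structures).
#'
#' @param structures list of `ppi_structure` (>= 2).
#' @param exclude optional selection string(s) of residues to drop.
#' @return data.frame (chain, resno, insert) with class `common_core`.
#' @export
common_core <- function(structures, exclude = NULL) {
  if (length(structures) < 2) stopf("need at least 2 structures")
  ins_key <- function(ins) ifelse(is.na(ins) | ins == "", ".", ins)
  keys <- lapply(structures, function(s) {
    ca <- s$atom[s$atom$elety == "CA" & is_heavy_atom(s$atom), , drop = FALSE]
    unique(paste(ca$chain, ca$resno, ins_key(ca$insert), sep = "|"))
  })
  core <- Reduce(intersect, keys)
  if (!is.null(exclude)) {
    ex <- parse_selection(exclude)
    for (i in seq_len(nrow(ex))) {
      drop <- paste(ex$chain[i], ex$start[i]:ex$end[i], ".", sep = "|")
      core <- setdiff(core, drop)
    }
  }
  if (length(core) == 0) stopf("empty common core across the ensemble")
  parts <- do.call(rbind, strsplit(core, "|", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    insert = ifelse(parts[, 3] == ".", "", parts[, 3]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("common_core", "data.frame")
  out
}

core_ca_indices <- function(structure, core) {
  at <- structure$atom
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  want <- paste(core$chain, core$resno, core$insert, sep = "|")
  idx <- vapply(want, function(k) {
    i <- which(key == k & at$elety == "CA" & is_heavy_atom(at))
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(idx)) stopf("a core residue lacks a C-alpha in this structure")
  unname(idx)
}

#' Coordinate PCA over a structure ensemble
#'
#' All members are superposed on the core C-alphas (first onto the chosen
#' reference, then twice onto the updated ensemble mean -- the standard
#' essential-dynamics convention), and the mean-centred 3N coordinate
#' vectors are decomposed by SVD.  Eigenvalues are the sample covariance
#' eigenvalues (divisor n - 1), in square Angstrom.
#'
#' @param structures list of `ppi_structure` (>= 3) or a `ppi_trajectory`.
#' @param core a `common_core`; computed automatically (no exclusions) when
#'   `NULL` and a structure list is given; for trajectories all C-alphas of
#'   the topology are used.
#' @param reference index of the initial superposition reference.
#' @return a `pca_result`: eigenvalues, variance fractions, scores
#'   (n x k), loadings (3N x k, orthonormal columns), mean vector, the core
#'   residue table and the superposed coordinate matrix `xyz_fitted`.
#' @export
coordinate_pca <- function(structures, core = NULL, reference = 1) {
  if (inherits(structures, "ppi_trajectory")) {
    traj <- structures
    structures <- lapply(seq_len(n_frames(traj)), function(i)
      frame_structure(traj, i))
  }
  n <- length(structures)
  if (n < 3) stopf("need at least 3 structures for PCA")
  if (is.null(core)) core <- common_core(structures)
  x <- t(vapply(structures, function(s) {
    idx <- core_ca_indices(s, core)
    mat_to_xyz(as.matrix(s$atom[idx, c("x", "y", "z")]))
  }, numeric(3L * nrow(core))))

  ref <- xyz_to_mat(x[reference, ])
  fit_all <- function(x, target) t(apply(x, 1, function(v)
    mat_to_xyz(kabsch_superpose(xyz_to_mat(v), target)$coords)))
  x <- fit_all(x, ref)
  for (it in 1:2) x <- fit_all(x, xyz_to_mat(colMeans(x)))

  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (max(abs(xc)) < 1e-9) stopf("zero variance: identical structures")
  s <- svd(xc)
  k <- sum(s$d > max(s$d) * 1e-10)
  lambda <- s$d[1:k]^2 / (n - 1)
  res <- list(mean = mu,
              eigenvalues = lambda,
              var_fractions = lambda / sum(lambda),
              scores = xc %*% s$v[, 1:k, drop = FALSE],
              loadings = s$v[, 1:k, drop = FALSE],
              core = core, n = n, xyz_fitted = x)
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> n=%d structures, %d core residues, %d PCs\n",
              x$n, nrow(x$core), length(x$eigenvalues)))
  vf <- utils::head(x$var_fractions, 5)
  cat("  variance fractions:", paste(sprintf("%.3f", vf), collapse = " "),
      if (length(x$var_fractions) > 5) "..." else "", "\n")
  invisible(x)
}

#' Per-residue fluctuation profile from PC loadings
#'
#' For residue i, `sqrt(sum_j lambda_j * |loading_j(i)|^2)` over the first
#' `k` PCs, where `|loading_j(i)|` is the norm of the residue's 3-vector
#' loading.  With `k` equal to the number of PCs this is exactly the RMSF
#' about the ensemble mean (divisor n - 1).
#'
#' @param pca a `pca_result`.
#' @param k number of leading PCs to aggregate (default 5, clipped to the
#'   available number).
#' @return data.frame (chain, resno, insert, fluctuation) in Angstrom.
#' @export
fluctuation_profile <- function(pca, k = 5) {
  npc <- length(pca$eigenvalues)
  if (k < 1 || k > npc) stopf("k must be in 1..%d", npc)
  nres <- nrow(pca$core)
  contrib <- numeric(nres)
  for (j in seq_len(k)) {
    lj <- xyz_to_mat(pca$loadings[, j])
    contrib <- contrib + pca$eigenvalues[j] * rowSums(lj^2)
  }
  out <- pca$core
  class(out) <- "data.frame"
  out$fluctuation <- sqrt(contrib)
  out
}
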