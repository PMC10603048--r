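#' Read a PDB file into a structure or trajectory
#'
#' Single-model files yield a `ppi_structure`; multi-MODEL files yield a
#' `ppi_trajectory` whose topology is the first model.  Alternate locations
#' are resolved to the highest-occupancy conformer (ties broken in favour of
#' altloc "A").  HETATM records are retained; waters (and monatomic ions when
#' `drop_ions = TRUE`) are dropped by default, matching the convention of
#' keeping active-site ligands while discarding solvent.
#'
#' @param path path to a PDB file containing at least one ATOM/HETATM record.
#' @param drop_waters drop water residues (HOH/WAT/TIP3/SOL/...)?
#' @param drop_ions drop common monatomic ion residues (NA/CL/MG/ZN/K/CA ions)?
#' @return a `ppi_structure` or `ppi_trajectory`.
#' @export
read_pdb <- function(path, drop_waters = TRUE, drop_ions = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stopf("unreadable PDB file '%s': %s", path,
                              conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stopf("no ATOM/HETATM records in %s", path)
  n_models <- nrow(pdb$xyz)

  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz_cols <- as.numeric(t(outer(keep - 1L, 1:3, function(i, k) 3L * i + k)))
  xyz <- pdb$xyz[, xyz_cols, drop = FALSE]

  drop <- rep(FALSE, nrow(at))
  if (drop_waters) drop <- drop | at$resid %in% water_resids
  if (drop_ions)
    drop <- drop | (at$type == "HETATM" &
                    at$resid %in% c("NA", "CL", "MG", "ZN", "K", "CA",
                                    "MN", "FE", "CU", "IOD", "BR"))
  if (any(drop)) {
    idx <- which(!drop)
    at <- at[idx, , drop = FALSE]
    xyz <- xyz[, as.numeric(t(outer((idx - 1L) * 3L, 1:3, `+`))), drop = FALSE]
  }
  if (nrow(at) == 0) stopf("no atoms left after water/ion filtering in %s", path)

  at <- normalise_atom_table(at, xyz[1, ])
  topo <- new_structure(at, model_id = basename(path))
  if (n_models == 1L) return(topo)
  new_trajectory(topo, xyz)
}

# keep, per (chain, resno, insert, elety), the highest-occupancy altloc;
# ties prefer altloc "A"; returns row indices to keep, in original order
resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno,
               ifelse(is.na(at$insert), "", at$insert), at$elety, at$type)
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys) {
    rows <- which(key == k)
    ord <- order(-occ[rows], alt[rows] != "A", alt[rows])
    keep[rows[-ord[1]]] <- FALSE
  }
  sort(which(keep))
}

normalise_atom_table <- function(at, xyz1) {
  ele <- at$elesy
  bad <- is.na(ele) | ele == ""
  if (any(bad))
    ele[bad] <- suppressWarnings(bio3d::atom2ele(at$elety[bad]))
  ele <- toupper(trimws(ele))
  m <- xyz_to_mat(xyz1)
  data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    resid = at$resid, chain = as.character(at$chain), resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = m[, 1], y = m[, 2], z = m[, 3],
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = ele, stringsAsFactors = FALSE)
}

new_structure <- function(atom, model_id = "model") {
  stopifnot(is.data.frame(atom))
  rownames(atom) <- NULL
  structure(list(atom = atom, model_id = model_id), class = "ppi_structure")
}

new_trajectory <- function(topology, xyz, frame_interval = NA_real_) {
  if (!inherits(topology, "ppi_structure")) stopf("topology must be a ppi_structure")
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology$atom))
    stopf("frame length (%d) does not match topology atom count (%d)",
          ncol(xyz) / 3, nrow(topology$atom))
  if (nrow(xyz) < 1) stopf("trajectory needs at least one frame")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval = frame_interval),
            class = "ppi_trajectory")
}

#' @export
print.ppi_structure <- function(x, ...) {
  ch <- unique(x$atom$chain)
  cat(sprintf("<ppi_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atom), nrow(unique(x$atom[c("chain", "resno", "insert")])),
              paste(ch, collapse = " ")))
  invisible(x)
}

#' @export
print.ppi_trajectory <- function(x, ...) {
  cat(sprintf("<ppi_trajectory> %d frames x %d atoms\n",
              nrow(x$xyz), nrow(x$topology$atom)))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

is_heavy_atom <- function(atom) !(atom$elesy %in% c("H", "D"))

# a structure for frame i of a trajectory
frame_structure <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stopf("frame index %d out of range", i)
  at <- traj$topology$atom
  m <- xyz_to_mat(traj$xyz[i, ])
  at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
  new_structure(at, model_id = sprintf("%s/frame%d", traj$topology$model_id, i))
}

structure_xyz <- function(s) mat_to_xyz(as.matrix(s$atom[, c("x", "y", "z")]))

set_structure_xyz <- function(s, xyz) {
  m <- xyz_to_mat(xyz)
  s$atom$x <- m[, 1]; s$atom$y <- m[, 2]; s$atom$z <- m[, 3]
  s
}

#' Write a structure or trajectory as a PDB file
#'
#' Round-trips atom names, residue numbering, chain identifiers and
#' coordinates at the PDB fixed-width precision of 3 decimals.  Trajectories
#' are written as multi-MODEL files.
#'
#' @param x a `ppi_structure` or `ppi_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "ppi_structure")) {
    at <- x$atom
    xyz <- matrix(structure_xyz(x), nrow = 1)
  } else if (inherits(x, "ppi_trajectory")) {
    at <- x$topology$atom
    xyz <- x$xyz
  } else stopf("x must be a ppi_structure or ppi_trajectory")
  if (any(xyz > 9999.999 | xyz < -999.999))
    stopf("coordinate exceeds the PDB fixed-width field (-999.999..9999.999)")
  bio3d::write.pdb(
    file = path, xyz = xyz, type = at$type, eleno = at$eleno,
    elety = at$elety, resid = at$resid, chain = at$chain, resno = at$resno,
    insert = ifelse(at$insert == "", NA, at$insert),
    o = at$o, b = at$b, elesy = at$elesy)
  invisible(path)
}

#' Select atoms from a structure
#'
#' Atoms are returned in residue order.  Hydrogens are excluded by default;
#' all analysis metrics in this package are heavy-atom based.
#'
#' @param structure a `ppi_structure`.
#' @param chain chain identifier (must exist).
#' @param residue_range optional integer vector `c(start, end)` (inclusive).
#' @param atom_names optional character vector of PDB atom names (e.g. "CA").
#' @param hydrogens include hydrogens?
#' @return a data.frame of atom records (possibly empty).
#' @export
select_atoms <- function(structure, chain, residue_range = NULL,
                         atom_names = NULL, hydrogens = FALSE) {
  at <- structure$atom
  if (!chain %in% at$chain) stopf("unknown chain identifier '%s'", chain)
  sel <- at$chain == chain
  if (!is.null(residue_range))
    sel <- sel & at$resno >= residue_range[1] & at$resno <= residue_range[2]
  if (!is.null(atom_names)) sel <- sel & at$elety %in% atom_names
  if (!hydrogens) sel <- sel & is_heavy_atom(at)
  out <- at[sel, , drop = FALSE]
  out[order(match(out$chain, unique(at$chain)), out$resno, out$insert), ,
      drop = FALSE]
}
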