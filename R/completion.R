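# Template-based completion of a missing partner fragment: backbone grafting
# from a template segment, sequence mutation to idealized C-beta sidechains,
# and ideal-geometry terminus extension.  No rotamer building and no energy
# minimization: downstream metrics are C-alpha/C-beta based, and steric
# clashes are reported rather than fixed.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

residue_split <- function(atom) {
  split(seq_len(nrow(atom)),
        factor(paste(atom$chain, atom$resno, atom$insert, sep = "|"),
               levels = unique(paste(atom$chain, atom$resno, atom$insert,
                                     sep = "|"))))
}

residue_atom_xyz <- function(atom, rows, name) {
  i <- rows[atom$elety[rows] == name]
  if (length(i) == 0) return(NULL)
  as.numeric(atom[i[1], c("x", "y", "z")])
}

make_atom_row <- function(elety, elesy, resid, chain, resno, xyz,
                          type = "ATOM") {
  data.frame(type = type, eleno = 0L, elety = elety, resid = resid,
             chain = chain, resno = as.integer(resno), insert = "",
             x = xyz[1], y = xyz[2], z = xyz[3], o = 1, b = 0,
             elesy = elesy, stringsAsFactors = FALSE)
}

renumber_elenos <- function(atom) {
  atom$eleno <- seq_len(nrow(atom))
  rownames(atom) <- NULL
  atom
}

# residue rows (in chain order) for a segment data.frame
segment_residue_rows <- function(structure, segs) {
  at <- structure$atom
  keep <- selection_indices(structure, segs, hydrogens = TRUE)
  sub <- at[keep, , drop = FALSE]
  rows <- residue_split(sub)
  lapply(rows, function(r) keep[r])
}

#' Graft a partner fragment from a template onto a target complex
#'
#' Copies the backbone (N, CA, C, O) of a template segment into the target,
#' assigns a new sequence and author numbering, and represents sidechains by
#' an idealized C-beta (absent for glycine).  The grafted backbone coincides
#' with the template segment by construction.
#'
#' @param target a `ppi_structure` (the complex being completed).
#' @param template a `ppi_structure` holding the donor segment.
#' @param template_selection selection string, e.g. `"B:7-43"`.
#' @param sequence one-letter sequence for the grafted residues, or `NULL`
#'   to keep the template identities.
#' @param start first author residue number of the graft in the target.
#' @param chain chain identifier for the grafted residues in the target
#'   (default: the template segment's chain).
#' @return the completed `ppi_structure`.
#' @export
graft_fragment <- function(target, template, template_selection,
                           sequence = NULL, start, chain = NULL) {
  segs <- parse_selection(template_selection, template)
  res_rows <- segment_residue_rows(template, segs)
  nres <- length(res_rows)
  if (nres == 0) stopf("template segment matches no residues")
  if (is.null(chain)) chain <- segs$chain[1]
  if (!is.null(sequence)) {
    seq1 <- strsplit(sequence, "")[[1]]
    if (length(seq1) != nres)
      stopf("sequence length (%d) does not match segment residue count (%d)",
            length(seq1), nres)
    bad <- setdiff(seq1, names(aa_three))
    if (length(bad) > 0) stopf("invalid one-letter code(s): %s",
                               paste(unique(bad), collapse = ""))
    new_names <- unname(aa_three[seq1])
  } else {
    new_names <- vapply(res_rows, function(r) template$atom$resid[r[1]],
                        character(1))
  }
  new_nums <- start + seq_len(nres) - 1L
  clash <- intersect(paste(chain, new_nums),
                     paste(target$atom$chain, target$atom$resno))
  if (length(clash) > 0)
    stopf("numbering collision with existing target residues: %s",
          paste(utils::head(clash, 5), collapse = "; "))

  tat <- template$atom
  built <- do.call(rbind, lapply(seq_len(nres), function(i) {
    r <- res_rows[[i]]
    bb <- lapply(BACKBONE_ATOMS, function(a) residue_atom_xyz(tat, r, a))
    names(bb) <- BACKBONE_ATOMS
    if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
      stopf("template residue %s:%d lacks a complete backbone",
            tat$chain[r[1]], tat$resno[r[1]])
    rows <- list()
    for (a in BACKBONE_ATOMS) if (!is.null(bb[[a]]))
      rows[[a]] <- make_atom_row(a, substr(a, 1, 1), new_names[i], chain,
                                 new_nums[i], bb[[a]])
    if (new_names[i] != "GLY")
      rows$CB <- make_atom_row("CB", "C", new_names[i], chain, new_nums[i],
                               place_cbeta(bb$N, bb$CA, bb$C))
    do.call(rbind, rows)
  }))
  new_structure(renumber_elenos(rbind(target$atom, built)),
                model_id = paste0(target$model_id, "+graft"))
}

#' Mutate a residue, replacing its sidechain by an idealized C-beta
#'
#' The backbone is preserved.  The C-beta is placed at 1.53 A from the
#' C-alpha with tetrahedral geometry from the N-CA-C frame (omitted for
#' glycine).  Mutating a residue to its current name is a no-op.
#'
#' @param structure a `ppi_structure`.
#' @param residue residue reference `"chain:resno"` (e.g. `"B:61"`).
#' @param new_name target three-letter residue name (standard 20).
#' @return the mutated `ppi_structure`.
#' @export
mutate_residue <- function(structure, residue, new_name) {
  new_name <- toupper(new_name)
  if (!is_standard_aa(new_name))
    stopf("unknown residue name '%s'", new_name)
  ref <- parse_res_ref(residue)
  at <- structure$atom
  rows <- which(at$chain == ref$chain & at$resno == ref$resno)
  if (length(rows) == 0) stopf("residue %s not found", residue)
  if (at$resid[rows[1]] == new_name) return(structure)
  bb_rows <- rows[at$elety[rows] %in% BACKBONE_ATOMS]
  n <- residue_atom_xyz(at, rows, "N")
  ca <- residue_atom_xyz(at, rows, "CA")
  c_ <- residue_atom_xyz(at, rows, "C")
  if (is.null(n) || is.null(ca) || is.null(c_))
    stopf("residue %s lacks a complete backbone", residue)
  keep <- at[bb_rows, , drop = FALSE]
  keep$resid <- new_name
  if (new_name != "GLY")
    keep <- rbind(keep, make_atom_row("CB", "C", new_name, ref$chain,
                                      ref$resno, place_cbeta(n, ca, c_)))
  out <- rbind(at[seq_len(nrow(at)) < min(rows), , drop = FALSE],
               keep,
               at[seq_len(nrow(at)) > max(rows), , drop = FALSE])
  new_structure(renumber_elenos(out), model_id = structure$model_id)
}

parse_res_ref <- function(x) {
  if (is.list(x)) return(x)
  m <- regmatches(x, regexec("^(.+):(-?[0-9]+)$", x))[[1]]
  if (length(m) != 3) stopf("malformed residue reference '%s'", x)
  list(chain = m[2], resno = as.integer(m[3]))
}

#' Extend a chain terminus with ideal-geometry residues
#'
#' New residues are built with ideal trans-peptide backbone geometry
#' (N-CA 1.46 A, CA-C 1.52 A, C-N 1.33 A) in either an extended
#' (phi = -140, psi = 135) or helical (phi = -57, psi = -47) conformation,
#' with idealized C-beta sidechains.  Steric clashes of the new residues
#' against the rest of the structure (heavy-atom pairs closer than 2 A)
#' are recorded in the `"clashes"` attribute, not fixed.
#'
#' @param structure a `ppi_structure`.
#' @param chain chain to extend.
#' @param sequence one-letter sequence to add (may be empty: no-op).  For a
#'   N-terminal extension the sequence is given N-to-C, ending at the
#'   existing terminus.
#' @param direction `"N"` or `"C"`.
#' @param conformation `"extended"` or `"helical"`.
#' @param clash_cutoff heavy-atom clash distance (A).
#' @return the extended `ppi_structure` (attribute `"clashes"`: data.frame
#'   of offending atom pairs).
#' @export
extend_terminus <- function(structure, chain, sequence,
                            direction = c("N", "C"),
                            conformation = c("extended", "helical"),
                            clash_cutoff = 2.0) {
  direction <- match.arg(direction)
  conformation <- match.arg(conformation)
  if (nchar(sequence) == 0) {
    attr(structure, "clashes") <- empty_clash_table()
    return(structure)
  }
  seq1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(seq1, names(aa_three))
  if (length(bad) > 0) stopf("invalid one-letter code(s): %s",
                             paste(unique(bad), collapse = ""))
  at <- structure$atom
  if (!chain %in% at$chain) stopf("unknown chain identifier '%s'", chain)
  ch_rows <- which(at$chain == chain)
  angles <- PHI_PSI[[conformation]]
  nres <- length(seq1)

  if (direction == "N") {
    first_no <- min(at$resno[ch_rows])
    rows <- ch_rows[at$resno[ch_rows] == first_no]
    seed <- list(N = residue_atom_xyz(at, rows, "N"),
                 CA = residue_atom_xyz(at, rows, "CA"),
                 C = residue_atom_xyz(at, rows, "C"))
    if (any(vapply(seed, is.null, logical(1))))
      stopf("terminal residue %s:%d lacks a complete backbone", chain, first_no)
    bb <- walk_backbone_n(seed$C, seed$CA, seed$N, nres,
                          angles["phi"], angles["psi"])
    new_nums <- first_no - rev(seq_len(nres))
    next_n <- c(bb[-1], list(seed))  # residue i+1's N closes each carbonyl
  } else {
    last_no <- max(at$resno[ch_rows])
    rows <- ch_rows[at$resno[ch_rows] == last_no]
    seed <- list(N = residue_atom_xyz(at, rows, "N"),
                 CA = residue_atom_xyz(at, rows, "CA"),
                 C = residue_atom_xyz(at, rows, "C"))
    if (any(vapply(seed, is.null, logical(1))))
      stopf("terminal residue %s:%d lacks a complete backbone", chain, last_no)
    bb <- walk_backbone_c(seed$N, seed$CA, seed$C, nres,
                          angles["phi"], angles["psi"])
    new_nums <- last_no + seq_len(nres)
    # virtual next N (from psi) closes the final carbonyl
    virt <- place_atom(bb[[nres]]$N, bb[[nres]]$CA, bb[[nres]]$C,
                       GEOM$b_c_n, GEOM$a_ca_c_n, angles["psi"])
    next_n <- c(bb[-1], list(list(N = virt)))
  }

  built <- do.call(rbind, lapply(seq_len(nres), function(i) {
    res3 <- unname(aa_three[seq1[i]])
    b <- bb[[i]]
    o <- place_carbonyl_o(b$CA, b$C, next_n[[i]]$N)
    rows <- list(
      make_atom_row("N", "N", res3, chain, new_nums[i], b$N),
      make_atom_row("CA", "C", res3, chain, new_nums[i], b$CA),
      make_atom_row("C", "C", res3, chain, new_nums[i], b$C),
      make_atom_row("O", "O", res3, chain, new_nums[i], o))
    if (res3 != "GLY")
      rows <- c(rows, list(make_atom_row("CB", "C", res3, chain,
                                         new_nums[i],
                                         place_cbeta(b$N, b$CA, b$C))))
    do.call(rbind, rows)
  }))

  if (direction == "N") {
    before <- at[seq_len(min(ch_rows) - 1), , drop = FALSE]
    after <- at[seq(min(ch_rows), nrow(at)), , drop = FALSE]
    out_at <- rbind(before, built, after)
  } else {
    out_at <- rbind(at[seq_len(max(ch_rows)), , drop = FALSE], built,
                    if (max(ch_rows) < nrow(at))
                      at[seq(max(ch_rows) + 1, nrow(at)), , drop = FALSE])
  }
  out <- new_structure(renumber_elenos(out_at), model_id = structure$model_id)
  attr(out, "clashes") <- clash_scan(built, at[at$chain != chain, ,
                                               drop = FALSE], clash_cutoff)
  out
}

empty_clash_table <- function() {
  data.frame(chain1 = character(), resno1 = integer(), elety1 = character(),
             chain2 = character(), resno2 = integer(), elety2 = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

# brute-force heavy-atom pair scan between two atom tables
clash_scan <- function(a, b, cutoff = 2.0) {
  a <- a[is_heavy_atom(a), , drop = FALSE]
  b <- b[is_heavy_atom(b), , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_clash_table())
  am <- as.matrix(a[, c("x", "y", "z")]); bm <- as.matrix(b[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(am^2), rep(1, nrow(bm))) +
            outer(rep(1, nrow(am)), rowSums(bm^2)) - 2 * am %*% t(bm))
  hits <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_clash_table())
  data.frame(chain1 = a$chain[hits[, 1]], resno1 = a$resno[hits[, 1]],
             elety1 = a$elety[hits[, 1]],
             chain2 = b$chain[hits[, 2]], resno2 = b$resno[hits[, 2]],
             elety2 = b$elety[hits[, 2]],
             distance = d[hits], stringsAsFactors = FALSE)
}
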