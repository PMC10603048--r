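# Selection strings: "A:61-89", "B:7-43,61-89" (segments on one chain) or a
# character vector mixing chains, e.g. c("B:7-43", "C:61-89").  A bare chain
# ("A") selects the chain's full observed residue range.

#' Parse a selection string into chain/range segments
#'
#' @param sel character vector of `chain[:start-end[,start-end...]]` strings.
#' @param structure optional `ppi_structure` used to resolve bare-chain
#'   selections to their observed residue range.
#' @return data.frame with columns chain, start, end.
#' @export
parse_selection <- function(sel, structure = NULL) {
  segs <- do.call(rbind, lapply(sel, function(s) {
    s <- trimws(s)
    if (!grepl(":", s, fixed = TRUE)) {
      if (is.null(structure))
        stopf("bare-chain selection '%s' needs a structure to resolve", s)
      at <- structure$atom[structure$atom$chain == s, , drop = FALSE]
      if (nrow(at) == 0) stopf("unknown chain identifier '%s'", s)
      return(data.frame(chain = s, start = min(at$resno), end = max(at$resno)))
    }
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stopf("malformed selection '%s'", s)
    chain <- parts[1]
    ranges <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    do.call(rbind, lapply(ranges, function(r) {
      m <- regmatches(r, regexec("^(-?[0-9]+)-(-?[0-9]+)$", r))[[1]]
      if (length(m) != 3) stopf("malformed residue range '%s' in '%s'", r, s)
      start <- as.integer(m[2]); end <- as.integer(m[3])
      if (end < start) stopf("inverted residue range '%s'", r)
      data.frame(chain = chain, start = start, end = end)
    }))
  }))
  rownames(segs) <- NULL
  segs
}

#' Define receptor and partner selections of a complex
#'
#' @param receptor selection string(s) for the receptor (e.g. `"A:122-403"`).
#' @param partner selection string(s) for the partner; several segments are
#'   allowed (e.g. `c("B:7-43", "B:61-89")`).
#' @param label free-text label (e.g. `"N-Myc 61-89"`).
#' @param structure optional `ppi_structure` to validate against (and to
#'   resolve bare-chain selections).
#' @return a `complex_def` object.
#' @export
complex_definition <- function(receptor, partner, label = "",
                               structure = NULL) {
  rec <- parse_selection(receptor, structure)
  par <- parse_selection(partner, structure)
  both <- rbind(cbind(rec, role = "receptor"), cbind(par, role = "partner"))
  # disjointness on (chain, residue)
  expand <- function(segs) unlist(lapply(seq_len(nrow(segs)), function(i)
    paste(segs$chain[i], segs$start[i]:segs$end[i])))
  if (length(intersect(expand(rec), expand(par))) > 0)
    stopf("receptor and partner selections overlap")
  cd <- structure(list(receptor = rec, partner = par, label = label),
                  class = "complex_def")
  if (!is.null(structure)) validate_complex(cd, structure)
  cd
}

validate_complex <- function(cdef, structure) {
  at <- structure$atom
  check <- function(segs, role) {
    for (i in seq_len(nrow(segs))) {
      if (!segs$chain[i] %in% at$chain)
        stopf("%s chain '%s' absent from structure", role, segs$chain[i])
      have <- at$resno[at$chain == segs$chain[i]]
      miss <- setdiff(segs$start[i]:segs$end[i], have)
      if (length(miss) > 0)
        stopf("%s residues missing from structure: %s:%s", role,
              segs$chain[i], paste(utils::head(miss, 5), collapse = ","))
    }
  }
  check(cdef$receptor, "receptor"); check(cdef$partner, "partner")
  invisible(cdef)
}

#' @export
print.complex_def <- function(x, ...) {
  fmt <- function(segs) paste(sprintf("%s:%d-%d", segs$chain, segs$start,
                                      segs$end), collapse = ", ")
  cat(sprintf("<complex_def> %s\n  receptor: %s\n  partner:  %s\n",
              x$label, fmt(x$receptor), fmt(x$partner)))
  invisible(x)
}

# atom-table row indices for a selection segments data.frame
selection_indices <- function(structure, segs, atom_names = NULL,
                              hydrogens = FALSE) {
  at <- structure$atom
  sel <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(segs)))
    sel <- sel | (at$chain == segs$chain[i] & at$resno >= segs$start[i] &
                  at$resno <= segs$end[i])
  if (!is.null(atom_names)) sel <- sel & at$elety %in% atom_names
  if (!hydrogens) sel <- sel & is_heavy_atom(at)
  which(sel)
}

#' Residue and heavy-atom counts of the partner fragment
#'
#' The residue count is summed over the declared segments as
#' `end - start + 1`; the heavy-atom count is the number of non-hydrogen
#' atoms observed in the partner selection.
#'
#' @param structure a `ppi_structure`.
#' @param cdef a `complex_def`.
#' @return list with `n_residues` and `n_heavy_atoms`.
#' @export
fragment_stats <- function(structure, cdef) {
  segs <- cdef$partner
  if (nrow(segs) == 0) stopf("empty partner selection")
  idx <- selection_indices(structure, segs, hydrogens = FALSE)
  if (length(idx) == 0) stopf("partner selection matches no atoms")
  list(n_residues = sum(segs$end - segs$start + 1L),
       n_heavy_atoms = length(idx))
}
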