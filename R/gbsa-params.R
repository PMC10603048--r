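# Per-atom parameters for MM-GBSA scoring: partial charge, Lennard-Jones
# well depth / Rmin-half, generalized-Born intrinsic radius (with HCT
# screening factor), and LCPO surface-area coefficients.

PARAM_COLS <- c("chain", "resno", "atomname", "charge", "eps", "rmin",
                "gb_radius", "screen", "lcpo_p1", "lcpo_p2", "lcpo_p3",
                "lcpo_p4", "lcpo_radius")

#' Read a per-atom parameter table
#'
#' Whitespace-delimited text with a header row; required columns:
#' `chain resno atomname charge eps rmin gb_radius lcpo_p1 lcpo_p2 lcpo_p3
#' lcpo_p4 lcpo_radius` (an optional `screen` column holds the HCT
#' descreening scale, defaulting to 1).  Units: charge in elementary
#' charges, eps in kcal/mol, radii in Angstrom.
#'
#' @param path path to the table.
#' @return a data.frame of class `atom_params`.
#' @export
read_atom_params <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"screen" %in% names(tab)) tab$screen <- 1
  missing <- setdiff(PARAM_COLS, names(tab))
  if (length(missing) > 0)
    stopf("parameter table lacks column(s): %s", paste(missing, collapse = ", "))
  validate_params(tab[PARAM_COLS])
}

validate_params <- function(tab) {
  if (any(tab$gb_radius <= 0) || any(tab$lcpo_radius <= 0) ||
      any(tab$rmin <= 0))
    stopf("all radii must be positive")
  if (any(tab$lcpo_radius < tab$gb_radius - 0.5))
    stopf("LCPO radius implausibly small relative to GB radius")
  class(tab) <- c("atom_params", "data.frame")
  tab
}

# element-based defaults (mbondi-like GB radii; generic LJ well depths)
ELEMENT_DEFAULTS <- data.frame(
  elesy = c("C", "N", "O", "S", "H", "P"),
  eps = c(0.086, 0.170, 0.210, 0.250, 0.0157, 0.200),
  rmin = c(1.908, 1.824, 1.661, 2.000, 0.600, 2.100),
  gb_radius = c(1.70, 1.55, 1.50, 1.80, 1.30, 1.85),
  lcpo_radius = c(1.70, 1.65, 1.60, 1.90, 1.20, 1.90),
  stringsAsFactors = FALSE)

# residue-level unit charges and their carrier atom preference
CHARGE_CARRIERS <- list(
  LYS = list(q = +1, atoms = c("NZ", "CB", "CA")),
  ARG = list(q = +1, atoms = c("NH1", "CZ", "CB", "CA")),
  ASP = list(q = -1, atoms = c("OD1", "CG", "CB", "CA")),
  GLU = list(q = -1, atoms = c("OE1", "CD", "CB", "CA")))

#' Auto-assign toy per-atom parameters from a structure
#'
#' Intended for synthetic/backbone-level models where no force field is
#' available: unit charges (+1 on Lys/Arg, -1 on Asp/Glu, placed on the
#' charged-group atom when present, else the C-beta), zero charge
#' elsewhere; element-based LJ parameters and mbondi-like GB radii; LCPO
#' coefficients `(1, -1, 0, 0)`, which are exact for isolated and pairwise
#' overlapping spheres.
#'
#' @param structure a `ppi_structure`.
#' @return an `atom_params` table covering every atom of the structure.
#' @export
toy_params <- function(structure) {
  at <- structure$atom
  ele <- at$elesy
  ele[!ele %in% ELEMENT_DEFAULTS$elesy] <- "C"
  m <- match(ele, ELEMENT_DEFAULTS$elesy)
  tab <- data.frame(
    chain = at$chain, resno = at$resno, atomname = at$elety,
    charge = 0,
    eps = ELEMENT_DEFAULTS$eps[m], rmin = ELEMENT_DEFAULTS$rmin[m],
    gb_radius = ELEMENT_DEFAULTS$gb_radius[m], screen = 1,
    lcpo_p1 = 1, lcpo_p2 = -1, lcpo_p3 = 0, lcpo_p4 = 0,
    lcpo_radius = ELEMENT_DEFAULTS$lcpo_radius[m],
    stringsAsFactors = FALSE)
  for (rows in residue_split(at)) {
    cc <- CHARGE_CARRIERS[[at$resid[rows[1]]]]
    if (is.null(cc)) next
    carrier <- NULL
    for (a in cc$atoms) {
      hit <- rows[at$elety[rows] == a]
      if (length(hit) > 0) { carrier <- hit[1]; break }
    }
    if (!is.null(carrier)) tab$charge[carrier] <- cc$q
  }
  validate_params(tab)
}

# align a parameter table to the atoms of a structure (one row per atom)
align_params <- function(structure, params) {
  at <- structure$atom
  key_at <- paste(at$chain, at$resno, at$elety)
  key_p <- paste(params$chain, params$resno, params$atomname)
  m <- match(key_at, key_p)
  if (anyNA(m))
    stopf("missing parameters for atom(s): %s",
          paste(utils::head(key_at[is.na(m)], 5), collapse = "; "))
  params[m, , drop = FALSE]
}
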