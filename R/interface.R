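# Interface metrics: residue contact maps, start-vs-end C-alpha separation
# maps, C-beta distance series/distributions and salt-bridge persistence.

residue_keys <- function(segs) {
  unlist(lapply(seq_len(nrow(segs)), function(i)
    paste0(segs$chain[i], ":", segs$start[i]:segs$end[i])))
}

# per-residue atom row indices for a selection, named by "chain:resno"
residue_rows_by_key <- function(structure, segs, atom_names = NULL) {
  at <- structure$atom
  keys <- residue_keys(segs)
  out <- lapply(keys, function(k) {
    ref <- parse_res_ref(k)
    rows <- which(at$chain == ref$chain & at$resno == ref$resno &
                  is_heavy_atom(at))
    if (!is.null(atom_names)) rows <- rows[at$elety[rows] %in% atom_names]
    rows
  })
  names(out) <- keys
  out
}

pair_min_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Residue-residue contact map of a complex
#'
#' A receptor/partner residue pair is in contact iff its minimum
#' inter-residue distance is strictly below `cutoff`.  `mode = "heavy"`
#' uses all heavy atoms (the field convention); `mode = "calpha"` uses
#' C-alphas only, appropriate for backbone/C-beta-only models.
#'
#' @param structure a `ppi_structure`.
#' @param cdef a `complex_def`.
#' @param cutoff contact distance in Angstrom (> 0); default 5.
#' @param mode `"heavy"` or `"calpha"`.
#' @return a `contact_map`: logical matrix (receptor rows, partner columns)
#'   with `cutoff` and `mode` attributes.
#' @export
contact_map <- function(structure, cdef, cutoff = 5.0,
                        mode = c("heavy", "calpha")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stopf("cutoff must be positive")
  an <- if (mode == "calpha") "CA" else NULL
  rec <- residue_rows_by_key(structure, cdef$receptor, an)
  par <- residue_rows_by_key(structure, cdef$partner, an)
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")])
  m <- matrix(FALSE, length(rec), length(par),
              dimnames = list(names(rec), names(par)))
  for (i in seq_along(rec)) {
    if (length(rec[[i]]) == 0) next
    for (j in seq_along(par)) {
      if (length(par[[j]]) == 0) next
      m[i, j] <- pair_min_dist(xyz[rec[[i]], , drop = FALSE],
                               xyz[par[[j]], , drop = FALSE]) < cutoff
    }
  }
  structure(m, cutoff = cutoff, mode = mode, class = c("contact_map",
                                                       "matrix"))
}

#' Change in receptor-partner C-alpha distances between two frames
#'
#' For every (receptor C-alpha, partner C-alpha) pair,
#' `delta_d = d(first frame) - d(last frame)`.  Positive values mean the
#' pair approached over the trajectory, negative values mean separation.
#' Distances are internal, so the map is invariant under rigid motions of
#' whole frames, and swapping the two frames negates it.
#'
#' @param trajectory a `ppi_trajectory` (>= 2 frames).
#' @param cdef a `complex_def`.
#' @param first_index,last_index frame indices (1-based; `last_index = -1`
#'   means the final frame).
#' @return a `separation_map`: numeric matrix (receptor rows, partner
#'   columns) with attributes `first_index`, `last_index`.
#' @export
separation_change <- function(trajectory, cdef, first_index = 1,
                              last_index = -1) {
  nf <- n_frames(trajectory)
  if (nf < 2) stopf("need at least 2 frames")
  if (last_index < 0) last_index <- nf + 1 + last_index
  if (first_index == last_index) stopf("first and last frames must differ")
  topo <- trajectory$topology
  rec <- residue_rows_by_key(topo, cdef$receptor, "CA")
  par <- residue_rows_by_key(topo, cdef$partner, "CA")
  rec_i <- vapply(rec, function(r) if (length(r)) r[1] else NA_integer_,
                  integer(1))
  par_i <- vapply(par, function(r) if (length(r)) r[1] else NA_integer_,
                  integer(1))
  dmat <- function(frame) {
    xa <- xyz_to_mat(trajectory$xyz[frame, ])[rec_i, , drop = FALSE]
    xb <- xyz_to_mat(trajectory$xyz[frame, ])[par_i, , drop = FALSE]
    sqrt(outer(rowSums(xa^2), rep(1, nrow(xb))) +
         outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb))
  }
  m <- dmat(first_index) - dmat(last_index)
  dimnames(m) <- list(names(rec), names(par))
  structure(m, first_index = first_index, last_index = last_index,
            class = c("separation_map", "matrix"))
}

new_distance_series <- function(values, pair, atom_type) {
  if (any(!is.finite(values)) || any(values <= 0))
    stopf("distance series must be positive and finite")
  structure(list(values = values, pair = pair, atom_type = atom_type),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s (%s), %d frames, median %.2f A\n",
              x$pair, x$atom_type, length(x$values),
              stats::median(x$values)))
  invisible(x)
}

cb_row <- function(at, ref) {
  rows <- which(at$chain == ref$chain & at$resno == ref$resno &
                is_heavy_atom(at))
  if (length(rows) == 0) stopf("residue %s:%d missing from topology",
                               ref$chain, ref$resno)
  cb <- rows[at$elety[rows] == "CB"]
  if (length(cb) > 0) list(row = cb[1], surrogate = FALSE)
  else {
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) == 0) stopf("residue %s:%d has neither CB nor CA",
                               ref$chain, ref$resno)
    list(row = ca[1], surrogate = TRUE)
  }
}

#' Per-frame C-beta--C-beta distance between two residues
#'
#' Glycine (or any C-beta-less residue) falls back to the C-alpha, and the
#' series is flagged as a surrogate.
#'
#' @param trajectory a `ppi_trajectory`.
#' @param res_a,res_b residue references `"chain:resno"`.
#' @return a `distance_series` (fields `values`, `pair`, `atom_type`, the
#'   latter `"CB"` or `"CA-surrogate"`).
#' @export
cb_distance_series <- function(trajectory, res_a, res_b) {
  at <- trajectory$topology$atom
  a <- cb_row(at, parse_res_ref(res_a))
  b <- cb_row(at, parse_res_ref(res_b))
  ca <- atom_xyz_cols(a$row); cb <- atom_xyz_cols(b$row)
  d <- sqrt(rowSums((trajectory$xyz[, ca, drop = FALSE] -
                     trajectory$xyz[, cb, drop = FALSE])^2))
  new_distance_series(d, paste(res_a, res_b, sep = "--"),
                      if (a$surrogate || b$surrogate) "CA-surrogate" else "CB")
}

#' Summary of a distance distribution
#'
#' @param series a `distance_series`.
#' @param threshold optional distance threshold (A) for the below-threshold
#'   frame fraction.
#' @param bin_width histogram bin width (A); bins start at 0 so edges are
#'   deterministic.
#' @return list with `median`, `iqr`, `frac_below`, `histogram`.
#' @export
distribution_summary <- function(series, threshold = NULL,
                                 bin_width = 0.25) {
  v <- series$values
  breaks <- seq(0, (ceiling(max(v) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(median = stats::median(v),
       iqr = stats::IQR(v, type = 7),
       frac_below = if (is.null(threshold)) NA_real_ else mean(v < threshold),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

ACIDIC_O <- c("OD1", "OD2", "OE1", "OE2")
BASIC_N <- c("NZ", "NH1", "NH2", "NE")

#' Salt-bridge distance series between an acidic and a basic residue
#'
#' Per frame, the minimum distance between the acidic carboxylate oxygens
#' (OD1/OD2/OE1/OE2) and the basic nitrogens (NZ, NH1/NH2/NE).  For
#' C-beta-only models the C-beta--C-beta distance is used and the series is
#' flagged as a surrogate.
#'
#' @param trajectory a `ppi_trajectory`.
#' @param acidic residue reference; must be ASP or GLU.
#' @param basic residue reference; must be LYS or ARG.
#' @return a `distance_series`.
#' @export
salt_bridge_series <- function(trajectory, acidic, basic) {
  at <- trajectory$topology$atom
  a <- parse_res_ref(acidic); b <- parse_res_ref(basic)
  arow <- which(at$chain == a$chain & at$resno == a$resno)
  brow <- which(at$chain == b$chain & at$resno == b$resno)
  if (length(arow) == 0) stopf("residue %s missing from topology", acidic)
  if (length(brow) == 0) stopf("residue %s missing from topology", basic)
  if (!at$resid[arow[1]] %in% c("ASP", "GLU"))
    stopf("acidic residue must be ASP or GLU (got %s)", at$resid[arow[1]])
  if (!at$resid[brow[1]] %in% c("LYS", "ARG"))
    stopf("basic residue must be LYS or ARG (got %s)", at$resid[brow[1]])
  ao <- arow[at$elety[arow] %in% ACIDIC_O]
  bn <- brow[at$elety[brow] %in% BASIC_N]
  if (length(ao) == 0 || length(bn) == 0) {
    s <- cb_distance_series(trajectory, acidic, basic)
    s$atom_type <- "CB-surrogate"
    return(s)
  }
  d <- vapply(seq_len(n_frames(trajectory)), function(f) {
    x <- xyz_to_mat(trajectory$xyz[f, ])
    pair_min_dist(x[ao, , drop = FALSE], x[bn, , drop = FALSE])
  }, numeric(1))
  new_distance_series(d, paste(acidic, basic, sep = "--"), "charged-group")
}

#' Fraction of frames with distance below a cutoff
#'
#' A salt bridge (or any monitored contact) is labelled persistent when the
#' below-cutoff fraction reaches 0.5.  The value is invariant under frame
#' reordering.
#'
#' @param series a `distance_series`.
#' @param cutoff distance cutoff in Angstrom (default 4, the standard
#'   N--O salt-bridge criterion).
#' @return fraction in `[0, 1]`, with attribute `persistent`.
#' @export
persistence <- function(series, cutoff = 4.0) {
  f <- mean(series$values < cutoff)
  structure(f, persistent = f >= 0.5)
}
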