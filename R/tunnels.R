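# Proximity of a partner to named receptor surface tunnels.  Tunnel
# *detection* is out of scope: tunnels are supplied as residue sets (the
# packaged Aurora A kinase-domain definitions use author numbering).

#' Define a named tunnel by its lining residues
#'
#' @param label tunnel name.
#' @param residues character vector like `c("E183", "I184", ...)` (one-letter
#'   amino-acid code + author residue number) or plain residue numbers.
#' @param metadata optional named list (e.g. radius/length/curvature in A).
#' @return a `tunnel_def` with columns `aa` (may be `NA`) and `resno`.
#' @export
tunnel_definition <- function(label, residues, metadata = list()) {
  if (length(residues) == 0) stopf("a tunnel needs at least one residue")
  m <- regmatches(residues, regexec("^([A-Za-z]?)([0-9]+)$", residues))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stopf("malformed tunnel residue(s): %s",
                      paste(residues[bad], collapse = ", "))
  df <- data.frame(
    aa = vapply(m, function(x) ifelse(x[2] == "", NA_character_,
                                      toupper(x[2])), character(1)),
    resno = vapply(m, function(x) as.integer(x[3]), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(label = label, residues = df, metadata = metadata),
            class = "tunnel_def")
}

#' @export
print.tunnel_def <- function(x, ...) {
  cat(sprintf("<tunnel_def> %s: %s\n", x$label,
              paste0(ifelse(is.na(x$residues$aa), "", x$residues$aa),
                     x$residues$resno, collapse = " ")))
  invisible(x)
}

#' Read tunnel definitions from a plain-text file
#'
#' One tunnel per line, `label: RES###,RES###,...`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return named list of `tunnel_def`.
#' @export
read_tunnel_definitions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stopf("malformed tunnel line: '%s'", l)
    tunnel_definition(trimws(parts[1]),
                      trimws(strsplit(parts[2], ",")[[1]]))
  })
  names(out) <- vapply(out, function(t) t$label, character(1))
  out
}

#' Packaged Aurora A kinase-domain tunnel definitions
#'
#' Two surface tunnels of the Aurora A kinase domain (author numbering):
#' tunnel 1 at the lower central lobe (E183 I184 H187 L188 K250 V252 H280)
#' and tunnel 2 at the N-terminal lobe (K166 L169 L178 V182 V206 L208).
#'
#' @return named list of two `tunnel_def`.
#' @export
aura_tunnels <- function() {
  read_tunnel_definitions(system.file("extdata", "aura_tunnels.txt",
                                      package = "ppistab"))
}

tunnel_cb_rows <- function(at, tunnel, chain) {
  vapply(seq_len(nrow(tunnel$residues)), function(i) {
    ref <- list(chain = chain, resno = tunnel$residues$resno[i])
    cb_row(at, ref)$row
  }, integer(1))
}

#' Minimum C-beta distance from a partner residue to a tunnel
#'
#' The minimum over the tunnel's lining residues of the C-beta--C-beta
#' distance (C-alpha surrogate for glycine).
#'
#' @param frame a `ppi_structure`.
#' @param tunnel a `tunnel_def`.
#' @param partner_res partner residue reference `"chain:resno"`.
#' @param chain receptor chain carrying the tunnel residues.
#' @return distance in Angstrom.
#' @export
min_distance_to_tunnel <- function(frame, tunnel, partner_res, chain) {
  at <- frame$atom
  trows <- tunnel_cb_rows(at, tunnel, chain)
  prow <- cb_row(at, parse_res_ref(partner_res))$row
  xyz <- as.matrix(at[, c("x", "y", "z")])
  min(sqrt(rowSums(sweep(xyz[trows, , drop = FALSE], 2, xyz[prow, ])^2)))
}

# per-frame min tunnel distance series for one partner residue
tunnel_distance_series <- function(trajectory, tunnel, partner_res, chain) {
  at <- trajectory$topology$atom
  trows <- tunnel_cb_rows(at, tunnel, chain)
  prow <- cb_row(at, parse_res_ref(partner_res))$row
  tcols <- lapply(trows, atom_xyz_cols)
  pcols <- atom_xyz_cols(prow)
  apply(trajectory$xyz, 1, function(v) {
    p <- v[pcols]
    min(vapply(tcols, function(tc) vnorm(v[tc] - p), numeric(1)))
  })
}

#' Partner residue closest to a tunnel over a trajectory
#'
#' The partner residue with the lowest median per-frame minimum distance
#' to the tunnel; ties are broken by the lower residue number.
#'
#' @param trajectory a `ppi_trajectory`.
#' @param tunnel a `tunnel_def`.
#' @param partner selection string(s) for the partner.
#' @param chain receptor chain carrying the tunnel residues.
#' @return list with `residue` (`"chain:resno"`), `median_distance`, and the
#'   per-residue medians (`medians`).
#' @export
closest_partner_residue <- function(trajectory, tunnel, partner, chain) {
  segs <- parse_selection(partner, trajectory$topology)
  keys <- residue_keys(segs)
  if (length(keys) == 0) stopf("empty partner selection")
  med <- vapply(keys, function(k)
    stats::median(tunnel_distance_series(trajectory, tunnel, k, chain)),
    numeric(1))
  resno <- vapply(keys, function(k) parse_res_ref(k)$resno, integer(1))
  ord <- order(med, resno)
  list(residue = keys[ord[1]], median_distance = unname(med[ord[1]]),
       medians = med)
}

#' Fraction of frames with the partner residue engaged with a tunnel
#'
#' A frame counts as engaged when the minimum C-beta distance to the tunnel
#' is strictly below `threshold`.
#'
#' @inheritParams min_distance_to_tunnel
#' @param trajectory a `ppi_trajectory`.
#' @param threshold engagement distance (A), default 8.
#' @return fraction in `[0, 1]`.
#' @export
engagement_fraction <- function(trajectory, tunnel, partner_res, chain,
                                threshold = 8.0) {
  d <- tunnel_distance_series(trajectory, tunnel, partner_res, chain)
  mean(d < threshold)
}
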