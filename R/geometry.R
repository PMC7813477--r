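# Ideal-geometry peptide construction (bond/angle/torsion placement).
# Used by the synthetic-data module to build toy folds with hand-countable
# contact sets.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D bonded to C with |CD| = bond, angle(B,C,D) = angle (deg) and
# torsion(A,B,C,D) = torsion (deg)
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

.GEO <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.521,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.5,
  a_n_ca_cb = 110.5, t_cb = -122.6, omega = 180
)

#' Build an ideal-geometry peptide from backbone dihedrals
#'
#' Constructs a polypeptide backbone (N, CA, C, O, plus CB on non-glycine
#' residues) with standard bond lengths and angles, trans peptide bonds, and
#' the requested phi/psi dihedrals. phi of residue 1 and psi of the last
#' residue are not defined by the construction.
#'
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled to
#'   `n`. `phi[1]` and `psi[n]` are ignored.
#' @param n Number of residues (defaults to the dihedral vector length).
#' @param resnames 3-letter residue names, recycled to `n`.
#' @param chain Chain identifier.
#' @return A `cdh_structure` with coordinates rounded to 3 decimals (PDB
#'   precision, so write/read cycles are exact).
#' @export
build_peptide <- function(phi, psi, n = max(length(phi), length(psi)),
                          resnames = "ALA", chain = "A") {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  resnames <- rep_len(resnames, n)
  g <- .GEO
  rows <- list()
  add <- function(nm, el, res, resnm, p) {
    rows[[length(rows) + 1L]] <<- tibble(
      atom = nm, element = el, resno = res, resname = resnm,
      chain = chain, x = p[1], y = p[2], z = p[3])
  }
  # residue 1 backbone in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  ang <- (180 - g$a_n_ca_c) * pi / 180
  C <- CA + g$b_ca_c * c(cos(ang), sin(ang), 0)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA <- place_atom(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- place_atom(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    add("N", "N", i, resnames[i], N)
    add("CA", "C", i, resnames[i], CA)
    add("C", "C", i, resnames[i], C)
    O_tor <- if (i < n) psi[i] + 180 else 0
    add("O", "O", i, resnames[i], place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, O_tor))
    if (resnames[i] != "GLY") {
      add("CB", "C", i, resnames[i], place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_cb))
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3); atoms$z <- round(atoms$z, 3)
  new_cdh_structure(atoms)
}

# rigid transform helper
transform_structure <- function(s, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  s$x <- round(xyz[, 1], 3); s$y <- round(xyz[, 2], 3); s$z <- round(xyz[, 3], 3)
  new_cdh_structure(as_tibble(s)[, c("atom", "element", "resno", "resname", "chain", "x", "y", "z")])
}
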